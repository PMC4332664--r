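test_that("average linkage reproduces a hand-computed dendrogram", {
  ## distances: d(1,2)=1, d(1,3)=4, d(2,3)=5, d(1,4)=8, d(2,4)=9, d(3,4)=2
  d <- matrix(0, 4, 4)
  d[1, 2] <- 1; d[1, 3] <- 4; d[2, 3] <- 5; d[1, 4] <- 8; d[2, 4] <- 9; d[3, 4] <- 2
  d <- d + t(d)
  h <- average_linkage(d)
  ## merges: {1,2}@1, {3,4}@2, then {{1,2},{3,4}}@(4+5+8+9)/4 = 6.5
  expect_equal(h$height, c(1, 2, 6.5))
  g <- cut_to_groups(h, K = 2)
  expect_equal(as.integer(g$groups), c(1, 1, 2, 2))
  expect_error(cut_to_groups(h, K = 5), "out of range")
  expect_error(average_linkage(matrix(c(0, NA, NA, 0), 2, 2)), "NA")
})

test_that("profile-correlation distance excludes the pair's own columns", {
  ## two nodes with identical external profiles must have distance ~0
  ## regardless of their direct connection strength
  w <- matrix(0.2, 5, 5); diag(w) <- 0
  w[1, 2] <- w[2, 1] <- 0.9
  w[1, 3] <- w[3, 1] <- 0.8; w[2, 3] <- w[3, 2] <- 0.8
  w[1, 4] <- w[4, 1] <- 0.1; w[2, 4] <- w[4, 2] <- 0.1
  D <- node_distance_matrix(w, method = "profile_correlation")
  expect_equal(D[1, 2], 0, tolerance = 1e-12)
  expect_equal(D, t(D))
  expect_equal(diag(D), rep(0, 5), ignore_attr = TRUE)
  D2 <- node_distance_matrix(w, method = "one_minus_connectivity")
  expect_equal(D2[1, 2], 1 - 0.9)
  expect_error(node_distance_matrix(matrix(1:9, 3, 3)), "symmetric")
})

test_that("intra/inter sums satisfy the conservation identity", {
  set.seed(5)
  for (rep in 1:5) {
    n <- 12
    w <- matrix(runif(n * n), n, n); w <- (w + t(w)) / 2; diag(w) <- 0
    g <- sample(1:3, n, replace = TRUE)
    gc <- group_connectivity(w, g)
    expect_lt(abs(sum(gc$intra) + sum(gc$inter) - gc$total_upper_triangle), 1e-10)
    expect_equal(gc$total_upper_triangle, sum(w[upper.tri(w)]))
  }
  ## hand-checked case
  w <- matrix(0, 4, 4)
  w[1, 2] <- 1; w[3, 4] <- 2; w[1, 3] <- 3; w[2, 4] <- 4
  w <- w + t(w)
  gc <- group_connectivity(w, c(1, 1, 2, 2))
  expect_equal(as.numeric(gc$intra), c(1, 2))
  expect_equal(as.numeric(gc$inter), 7)
})

test_that("weighted clustering coefficient matches brute force", {
  set.seed(6)
  for (rep in 1:5) {
    n <- 8
    w <- matrix(runif(n * n), n, n); w <- (w + t(w)) / 2; diag(w) <- 0
    if (rep == 2) w[w < 0.4] <- 0  # sparse variant exercises the degree term
    expect_equal(unname(weighted_clustering_coefficient(w)), brute_clustering(w),
                 tolerance = 1e-12)
  }
  ## scale invariance
  w <- matrix(runif(25), 5, 5); w <- (w + t(w)) / 2; diag(w) <- 0
  expect_equal(weighted_clustering_coefficient(w),
               weighted_clustering_coefficient(w * 37))
  ## guards
  expect_error(weighted_clustering_coefficient(-w), "nonnegative")
  expect_warning(C0 <- weighted_clustering_coefficient(matrix(0, 3, 3)), "all-zero")
  expect_equal(unname(C0), rep(0, 3))
})

test_that("clustering coefficient is 1 on a complete unit-weight graph", {
  w <- matrix(1, 6, 6); diag(w) <- 0
  expect_equal(unname(weighted_clustering_coefficient(w)), rep(1, 6))
})

test_that("event-related clustering follows the c1 contract", {
  ev <- c(0.4, 0.2); bl <- c(0.2, 0.4)
  out <- event_related_clustering(ev, bl)
  expect_equal(as.numeric(out), c(1, -0.5))
  expect_error(event_related_clustering(1:3, 1:2), "match")
})

test_that("partition relabeling aligns group identities", {
  ref <- rep(1:3, each = 4)
  est <- rep(c(3, 1, 2), each = 4)  # same partition, permuted labels
  expect_equal(relabel_partition(est, ref), ref)
})
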