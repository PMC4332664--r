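test_that("spearman_rho matches R's tie-corrected Spearman", {
  set.seed(1)
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)  # repeated value exercises mid-ranks
  y <- c(2, 7, 1, 8, 2, 8, 1, 8)
  expect_equal(spearman_rho(x, y), cor(x, y, method = "spearman"))
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rho(1:2, 1:2), "lengths")
})

test_that("enumeration helpers are complete and duplicate-free", {
  S <- lpsnet:::all_sign_flips(4)
  expect_equal(dim(S), c(4, 16))
  expect_equal(nrow(unique(t(S))), 16)
  expect_true(all(S %in% c(-1, 1)))
  P <- lpsnet:::all_permutations(4)
  expect_equal(dim(P), c(24, 4))
  expect_equal(nrow(unique(P)), 24)
  expect_true(all(apply(P, 1, function(r) identical(sort(r), 1:4))))
})

test_that("observed paired t statistic matches t.test", {
  set.seed(2)
  A <- matrix(rnorm(10 * 3), 10, 3)
  B <- matrix(rnorm(10 * 3), 10, 3)
  res <- paired_tmax(A, B, scheme = "exhaustive")
  for (v in 1:3)
    expect_equal(unname(res$statistic[v]),
                 unname(t.test(A[, v], B[, v], paired = TRUE)$statistic),
                 tolerance = 1e-12)
})

test_that("exhaustive corrected p-values are exact for a tiny family", {
  ## n = 3 subjects, one variable: 8 sign patterns, |t| is maximized by
  ## the all-same-sign patterns, so the corrected p of the observed data
  ## must be 2/8 when all differences share a sign
  A <- matrix(c(1, 2, 3), 3, 1); B <- matrix(0, 3, 1)
  res <- paired_tmax(A, B, scheme = "exhaustive")
  expect_equal(res$scheme, "exhaustive")
  expect_equal(res$n_permutations, 8)
  expect_equal(unname(res$p_corrected), 2 / 8)
})

test_that("Monte-Carlo agrees with exhaustive enumeration (paired)", {
  set.seed(3)
  A <- matrix(rnorm(8 * 5), 8, 5) + 0.5
  B <- matrix(rnorm(8 * 5), 8, 5)
  ex <- paired_tmax(A, B, scheme = "exhaustive")
  mc <- paired_tmax(A, B, n_perm = 49999, seed = 11, scheme = "monte_carlo")
  expect_lt(max(abs(ex$p_corrected - mc$p_corrected)), 0.01)
})

test_that("Monte-Carlo agrees with exhaustive enumeration (Spearman)", {
  set.seed(4)
  x <- rnorm(6)
  Y <- matrix(rnorm(6 * 4), 6, 4); Y[, 1] <- x + rnorm(6, sd = 0.3)
  ex <- max_stat_spearman(x, Y, scheme = "exhaustive")
  mc <- max_stat_spearman(x, Y, n_perm = 49999, seed = 12, scheme = "monte_carlo")
  expect_equal(ex$n_permutations, 720)
  expect_lt(max(abs(ex$p_corrected - mc$p_corrected)), 0.02)
})

test_that("zero-variance and constant variables are handled explicitly", {
  A <- matrix(rnorm(12), 6, 2); A[, 2] <- 5
  B <- A; B[, 1] <- B[, 1] + rnorm(6)
  res <- paired_tmax(A, B)
  expect_true(res$zero_variance[2])
  expect_equal(unname(res$statistic[2]), 0)
  x <- rnorm(6); Y <- cbind(rnorm(6), rep(1, 6))
  rs <- max_stat_spearman(x, Y)
  expect_true(rs$flagged_constant[2])
  expect_true(is.na(rs$p_corrected[2]))
  expect_false(is.na(rs$p_corrected[1]))
})

test_that("the corrected p-value is monotone in the observed statistic", {
  set.seed(6)
  A <- matrix(rnorm(8 * 6), 8, 6)
  A[, 1] <- A[, 1] + 2          # strong effect
  A[, 2] <- A[, 2] + 0.3        # weak effect
  res <- paired_tmax(A, matrix(0, 8, 6), scheme = "exhaustive")
  o <- order(abs(res$statistic))
  expect_true(all(diff(res$p_corrected[o]) <= 1e-12))
  ## corrected never below uncorrected
  expect_true(all(res$p_corrected >= res$p_uncorrected - 1e-12))
})
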