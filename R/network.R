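## Sub-network identification and weighted graph measures.

#' Node distance matrix for dendrogram clustering
#'
#' Two distances are available. `profile_correlation` (default): one minus
#' the Pearson correlation between two nodes' connection profiles (their
#' rows of the connectivity matrix, excluding the two columns involving the
#' pair itself) -- nodes sharing a similar connection pattern with the rest
#' of the brain end up close. `one_minus_connectivity`: `1 - conn_ij`
#' directly.
#'
#' @param conn A `connectivity_matrix` or symmetric numeric matrix.
#' @param method `"profile_correlation"` or `"one_minus_connectivity"`.
#' @return Symmetric distance matrix with zero diagonal; zero-variance
#'   profiles get distance 1 to everything and are flagged in attribute
#'   `"constant_rows"`.
#' @export
node_distance_matrix <- function(conn, method = c("profile_correlation",
                                                  "one_minus_connectivity")) {
  method <- match.arg(method)
  w <- if (is.list(conn)) conn$values else conn
  if (!isTRUE(all.equal(w, t(w), tolerance = 1e-8)))
    stop("connectivity matrix must be symmetric")
  n <- nrow(w)
  d <- matrix(0, n, n)
  constant <- integer(0)
  if (method == "one_minus_connectivity") {
    d <- 1 - w
    diag(d) <- 0
  } else {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      xi <- w[i, -c(i, j)]; xj <- w[j, -c(i, j)]
      if (stats::sd(xi) < 1e-15 || stats::sd(xj) < 1e-15) {
        d[i, j] <- d[j, i] <- 1
        constant <- union(constant, c(i, j)[c(stats::sd(xi) < 1e-15,
                                              stats::sd(xj) < 1e-15)])
      } else {
        d[i, j] <- d[j, i] <- 1 - stats::cor(xi, xj)
      }
    }
  }
  rownames(d) <- colnames(d) <- rownames(w) %||%
    (if (is.list(conn)) conn$roi_labels else NULL)
  attr(d, "method") <- method
  attr(d, "constant_rows") <- constant
  d
}

#' Average-linkage (UPGMA) dendrogram
#'
#' Hierarchical agglomeration where the distance between two clusters is the
#' unweighted mean of all member pair distances; merge heights are
#' non-decreasing.
#'
#' @param dist_matrix Symmetric distance matrix (or `dist`).
#' @return An `hclust` object (merge table, heights, leaf order).
#' @export
average_linkage <- function(dist_matrix) {
  if (is.matrix(dist_matrix)) {
    if (any(is.na(dist_matrix))) stop("NaN/NA distances are not allowed")
    dist_matrix <- stats::as.dist(dist_matrix)
  }
  if (any(is.na(dist_matrix))) stop("NaN/NA distances are not allowed")
  stats::hclust(dist_matrix, method = "average")
}

#' Cut a dendrogram into K groups
#'
#' Removes the K-1 highest merges, yielding the K clusters a horizontal cut
#' of the dendrogram produces. This makes the qualitative
#' dendrogram-plus-visual-inspection step deterministic and reproducible;
#' the dendrogram is kept in the result so group membership can be revised
#' by eye.
#'
#' @param dendrogram An `hclust` object from [average_linkage()].
#' @param K Number of groups, `1 <= K <=` number of leaves.
#' @return Object of class `network_partition`: `groups` (integer
#'   membership), `K`, `dendrogram`.
#' @export
cut_to_groups <- function(dendrogram, K = 4L) {
  n <- length(dendrogram$order)
  if (K < 1L || K > n) stop("K out of range")
  g <- stats::cutree(dendrogram, k = K)
  structure(list(groups = g, K = as.integer(K), dendrogram = dendrogram),
            class = "network_partition")
}

#' Intra- and inter-group connectivity sums
#'
#' Intra-group connectivity of group g: the sum over all non-repeated pairs
#' inside g of their connectivity values. Inter-group connectivity of groups
#' g and h: the sum over all pairs with one node in each. The sums satisfy
#' the conservation identity: total intra plus total inter equals the full
#' upper-triangle sum.
#'
#' @param conn A `connectivity_matrix` or symmetric matrix (c1 or c2).
#' @param partition A `network_partition`, or an integer membership vector.
#' @return Object of class `group_connectivity`: `intra` (named vector per
#'   group), `inter` (named vector per group pair `"g:h"`),
#'   `total_upper_triangle`.
#' @export
group_connectivity <- function(conn, partition) {
  w <- if (is.list(conn)) conn$values else conn
  g <- if (inherits(partition, "network_partition")) partition$groups else partition
  if (length(g) != nrow(w)) stop("partition does not cover the matrix's ROIs")
  ids <- sort(unique(g))
  intra <- vapply(ids, function(k) {
    idx <- which(g == k)
    sum(w[idx, idx][upper.tri(diag(length(idx)))])
  }, numeric(1))
  names(intra) <- as.character(ids)
  if (length(ids) > 1L) {
    prs <- utils::combn(ids, 2L)
    inter <- vapply(seq_len(ncol(prs)), function(j)
      sum(w[g == prs[1, j], g == prs[2, j], drop = FALSE]), numeric(1))
    names(inter) <- apply(prs, 2L, paste, collapse = ":")
  } else inter <- numeric(0)
  structure(list(intra = intra, inter = inter,
                 total_upper_triangle = sum(w[upper.tri(w)])),
            class = "group_connectivity")
}

#' Weighted clustering coefficient (fully weighted, no thresholding)
#'
#' Per node i, the geometric-mean triangle intensity
#' `C_i = sum_{j != h != i} (w'_ij w'_ih w'_jh)^(1/3) / (k_i (k_i - 1))`
#' where `w' = w / max(w)` and `k_i` counts i's nonzero-weight neighbours.
#' Values lie in `[0, 1]`; the coefficient is invariant under global positive
#' rescaling of the weights.
#'
#' @param conn A `connectivity_matrix` or symmetric nonnegative matrix with
#'   zero diagonal.
#' @return Numeric vector of per-node coefficients (named by ROI labels when
#'   available). An all-zero matrix gives all-zero output with a warning.
#' @export
weighted_clustering_coefficient <- function(conn) {
  w <- if (is.list(conn)) conn$values else conn
  if (any(w < 0)) stop("weights must be nonnegative")
  if (any(diag(w) != 0)) stop("diagonal must be zero")
  n <- nrow(w)
  mx <- max(w)
  if (mx == 0) {
    warning("all-zero connectivity matrix: clustering coefficients are all zero")
    return(stats::setNames(numeric(n), rownames(w)))
  }
  wh <- (w / mx)^(1 / 3)
  num <- diag(wh %*% wh %*% wh)   # ordered (j, h) triangle paths through i
  k <- rowSums(w > 0)
  C <- ifelse(k > 1, num / (k * (k - 1)), 0)
  labs <- rownames(w) %||% (if (is.list(conn)) conn$roi_labels else NULL)
  if (!is.null(labs)) names(C) <- labs
  C
}

#' Event-related clustering coefficient
#'
#' Baseline normalization of per-node clustering coefficients, with the same
#' contract as [event_related_index()]: relative change of the SDP-window
#' coefficient with respect to the baseline-window coefficient.
#'
#' @param event_C,baseline_C Numeric vectors of per-node coefficients.
#' @param eps Floor for the baseline denominator.
#' @return Numeric vector of event-related coefficients; attribute
#'   `"floored"` marks nodes whose baseline fell below `eps`.
#' @export
event_related_clustering <- function(event_C, baseline_C, eps = 1e-6) {
  if (length(event_C) != length(baseline_C)) stop("coefficient vectors must match")
  den <- pmax(baseline_C, eps)
  out <- (event_C - baseline_C) / den
  attr(out, "floored") <- which(baseline_C < eps)
  out
}
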