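## Standardized minimum-norm (sLORETA-style) inverse for ROI-centroid sources.

#' Build a standardized minimum-norm inverse operator
#'
#' Minimum-norm weights `W = K' (K K' + lambda H)^+` with `H` the
#' average-reference centering matrix and `+` the Moore-Penrose
#' pseudo-inverse, standardized per source by the square root of the
#' corresponding diagonal entry of the resolution matrix `W K`. The
#' standardization gives the operator its zero-localization-error property
#' for noiseless single sources. Sources are scalar (fixed orientation), one
#' per ROI centroid.
#'
#' @param leadfield A [make_leadfield()] result or list with a `gain` matrix
#'   (channels x sources).
#' @param lambda Regularization; default `1e-4 * trace(K K') / channels`.
#' @return Object of class `inverse_operator`: `weights` (standardized,
#'   sources x channels), `raw_weights`, `standardization` (per-source
#'   factors, > 0), `lambda`.
#' @export
build_inverse_operator <- function(leadfield, lambda = NULL) {
  K <- if (is.list(leadfield)) leadfield$gain else leadfield
  if (!is.matrix(K) || all(K == 0)) stop("leadfield must be a nonzero matrix")
  nc <- nrow(K)
  if (is.null(lambda)) lambda <- 1e-4 * sum(K * K) / nc
  if (lambda < 0) stop("lambda must be >= 0")
  H <- diag(nc) - matrix(1 / nc, nc, nc)
  W <- t(K) %*% MASS::ginv(K %*% t(K) + lambda * H)
  R <- W %*% K
  s <- sqrt(pmax(diag(R), 0))
  if (any(s <= 0)) stop("non-positive standardization factor: degenerate leadfield column")
  structure(list(weights = W / s, raw_weights = W, standardization = s,
                 resolution = R, lambda = lambda,
                 roi_labels = if (is.list(leadfield)) leadfield$roi_labels else NULL),
            class = "inverse_operator")
}

#' Apply an inverse operator to channel epochs
#'
#' Linear per-sample mapping of channel vectors to standardized source
#' estimates; superposition holds exactly.
#'
#' @param epochs An `epoch_set` (trials x channels x samples) or a
#'   channels x samples matrix.
#' @param inverse_operator A [build_inverse_operator()] result.
#' @return A `source_epochs` object (or matrix for matrix input).
#' @export
apply_inverse <- function(epochs, inverse_operator) {
  W <- inverse_operator$weights
  if (is.matrix(epochs)) {
    if (nrow(epochs) != ncol(W)) stop("channel count does not match operator")
    return(W %*% epochs)
  }
  d <- epochs$data
  if (dim(d)[2] != ncol(W)) stop("channel count does not match operator")
  Tn <- dim(d)[1]; n <- dim(d)[3]
  X <- matrix(aperm(d, c(2L, 3L, 1L)), dim(d)[2], n * Tn)
  S <- W %*% X
  dim(S) <- c(nrow(W), n, Tn)
  structure(list(
    data = aperm(S, c(3L, 1L, 2L)),
    sampling_rate = epochs$sampling_rate,
    window_tag = epochs$window_tag,
    subject = epochs$subject,
    condition = epochs$condition,
    roi_labels = inverse_operator$roi_labels %||% paste0("S", seq_len(nrow(W))),
    band_state = epochs$band_state
  ), class = "source_epochs")
}
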