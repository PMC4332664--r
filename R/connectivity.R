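## Band-limited lagged phase synchronization and event-related indices.

#' Trial-averaged phase cross-spectra in a frequency band
#'
#' Per trial, the discrete Fourier coefficients of each ROI at the band's
#' bins are normalized to unit modulus (phase-only, as in phase
#' synchronization measures); their pairwise cross-products are averaged over
#' trials first, then over the band bins. The result is a Hermitian matrix
#' of complex coherencies with unit diagonal.
#'
#' @param source_epochs A `source_epochs` object (trials x ROIs x samples)
#'   or a plain 3-D array plus `sampling_rate`.
#' @param band Band limits in Hz, inside `(0, Nyquist)`.
#' @param sampling_rate Required when `source_epochs` is a bare array.
#' @return Object of class `cross_spectra`: `rho` (complex Hermitian matrix),
#'   `band`, `n_trials`, `n_bins`, `window_tag`, `roi_labels`.
#' @export
band_cross_spectra <- function(source_epochs, band = c(10, 12), sampling_rate = NULL) {
  if (is.list(source_epochs)) {
    d <- source_epochs$data
    fs <- source_epochs$sampling_rate
    wt <- source_epochs$window_tag
    rl <- source_epochs$roi_labels
  } else {
    d <- source_epochs
    fs <- sampling_rate
    wt <- NULL; rl <- NULL
    if (is.null(fs)) stop("sampling_rate is required for array input")
  }
  Tn <- dim(d)[1]; R <- dim(d)[2]; n <- dim(d)[3]
  if (Tn < 2L) stop("need at least 2 trials")
  if (band[1] <= 0 || band[2] >= fs / 2 || band[2] <= band[1])
    stop("band must lie inside (0, Nyquist)")
  kb <- band_bins(band, fs, n)
  B <- length(kb)
  ## DFT at the band bins only: E is n x B
  tt <- seq_len(n) - 1L
  E <- exp(-2i * pi * outer(tt, kb) / n)
  ## all trials at once: rows of m are (trial, ROI) pairs, columns samples
  m <- matrix(d, Tn * R, n)
  Cf <- m %*% E                                    # (Tn*R) x B complex
  Cf <- Cf / pmax(Mod(Cf), .Machine$double.xmin)   # unit modulus per coefficient
  rho <- matrix(0i, R, R)
  for (b in seq_len(B)) {
    Fb <- matrix(Cf[, b], Tn, R)
    rho <- rho + t(Fb) %*% Conj(Fb) / Tn           # trial-averaged per bin
  }
  rho <- rho / B                                   # trials then bins
  rho <- (rho + Conj(t(rho))) / 2                  # enforce Hermitian symmetry
  diag(rho) <- 1 + 0i
  structure(list(rho = rho, band = band, n_trials = Tn, n_bins = B,
                 window_tag = wt, roi_labels = rl),
            class = "cross_spectra")
}

#' Lagged phase synchronization matrix
#'
#' For each pairwise complex coherency `rho`, the lagged phase
#' synchronization `Im(rho)^2 / (1 - Re(rho)^2)`: the connectivity remaining
#' after the instantaneous (zero-lag) component is partialled out, which
#' immunizes the measure against volume conduction. The degenerate case
#' `Re(rho)^2 = 1` (identical signals, purely instantaneous) maps to 0.
#'
#' @param cross_spectra A [band_cross_spectra()] result, or a complex
#'   Hermitian matrix of coherencies.
#' @param tol Degeneracy tolerance on `1 - Re(rho)^2`.
#' @return Object of class `connectivity_matrix`: symmetric `values` in
#'   `[0, 1]` with zero diagonal, `normalization = "absolute"`, plus band and
#'   window metadata.
#' @export
lagged_phase_synchronization <- function(cross_spectra, tol = 1e-12) {
  cs <- cross_spectra
  rho <- if (is.list(cs)) cs$rho else cs
  if (any(Mod(rho) > 1 + 1e-9))
    stop("numerical integrity error: |rho| > 1")
  v <- lps_from_rho(rho, tol = tol)
  v <- (v + t(v)) / 2
  diag(v) <- 0
  structure(list(values = v,
                 normalization = "absolute",
                 band = if (is.list(cs)) cs$band else NULL,
                 n_trials = if (is.list(cs)) cs$n_trials else NULL,
                 window_tag = if (is.list(cs)) cs$window_tag else NULL,
                 roi_labels = if (is.list(cs)) cs$roi_labels else NULL),
            class = "connectivity_matrix")
}

#' Event-related (baseline-normalized) connectivity index
#'
#' The c1 index: elementwise relative change of the SDP-window connectivity
#' with respect to the baseline window,
#' `(event - baseline) / max(baseline, eps)`. Entries whose baseline falls
#' below the floor `eps` are computed against `eps` and flagged in the
#' output metadata. The companion c2 index is simply the untouched absolute
#' event-window matrix.
#'
#' @param event_conn,baseline_conn `connectivity_matrix` objects with
#'   `normalization = "absolute"`, same band and ROIs.
#' @param eps Floor for the baseline denominator.
#' @param ratio If `TRUE`, use the ratio `event / max(baseline, eps)` instead
#'   of the relative change.
#' @return A `connectivity_matrix` with `normalization = "event_related"`
#'   (values may be negative); attribute `"floored"` marks entries where the
#'   baseline floor engaged.
#' @export
event_related_index <- function(event_conn, baseline_conn, eps = 1e-6, ratio = FALSE) {
  ev <- event_conn$values; bl <- baseline_conn$values
  if (!identical(dim(ev), dim(bl))) stop("matrices must have matching ROIs")
  if (!is.null(event_conn$band) && !is.null(baseline_conn$band) &&
      !isTRUE(all.equal(event_conn$band, baseline_conn$band)))
    stop("matrices must share the same band")
  if (!identical(event_conn$normalization, "absolute") ||
      !identical(baseline_conn$normalization, "absolute"))
    stop("both inputs must be absolute (un-normalized) connectivity")
  den <- pmax(bl, eps)
  vals <- if (ratio) ev / den else (ev - bl) / den
  diag(vals) <- 0
  out <- structure(list(values = vals, normalization = "event_related",
                        band = event_conn$band, n_trials = event_conn$n_trials,
                        window_tag = event_conn$window_tag,
                        roi_labels = event_conn$roi_labels),
                   class = "connectivity_matrix")
  attr(out, "floored") <- which(bl < eps & upper.tri(bl), arr.ind = TRUE)
  out
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %d x %d, %s", nrow(x$values), ncol(x$values),
              x$normalization))
  if (!is.null(x$band)) cat(sprintf(", band %.1f-%.1f Hz", x$band[1], x$band[2]))
  if (!is.null(x$window_tag)) cat(", window ", x$window_tag)
  cat("\n")
  invisible(x)
}
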