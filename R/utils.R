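#' @keywords internal
"_PACKAGE"

## NULL coalescing
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Brodmann-style ROI labels
#'
#' Labels for the 84 cortical regions of interest used throughout the package:
#' 42 Brodmann areas per hemisphere, written as area number plus hemisphere
#' (e.g. `"44R"`, `"7L"`). The left-hemisphere labels come first.
#'
#' @param n_rois Number of ROIs (must be even; default 84).
#' @return Character vector of length `n_rois`.
#' @export
roi_labels <- function(n_rois = 84L) {
  if (n_rois %% 2L != 0L) stop("n_rois must be even (equal split across hemispheres)")
  ## Brodmann areas 1-11 and 17-47 give the 42 classically charted cortical areas
  bas <- c(1:11, 17:47)
  half <- n_rois %/% 2L
  if (half > length(bas)) bas <- seq_len(half)
  bas <- bas[seq_len(half)]
  c(paste0(bas, "L"), paste0(bas, "R"))
}

## Evaluate expr under a temporary RNG state seeded with `seed`,
## restoring the caller's RNG afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

## Derive a stream-specific 31-bit seed from a base seed and integer tags.
derive_seed <- function(seed, ...) {
  tags <- c(...)
  x <- as.double(seed) %% 2147483647
  for (t in tags) x <- (x * 69069 + as.double(t) * 104729 + 12345) %% 2147483647
  as.integer(x)
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name))
  if (positive && x <= 0) stop(sprintf("'%s' must be > 0", name))
  invisible(x)
}

## DFT bin indices (k, frequency = k * fs / n) falling inside [low, high]
band_bins <- function(band, fs, n) {
  df <- fs / n
  lo <- ceiling(band[1] / df - 1e-9)
  hi <- floor(band[2] / df + 1e-9)
  k <- if (hi < lo) integer(0) else seq.int(lo, hi)
  k <- k[k >= 1 & k <= floor((n - 1) / 2)]
  if (!length(k)) stop("band contains no DFT bins at this epoch length", call. = FALSE)
  k
}
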