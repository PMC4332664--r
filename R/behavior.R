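## Response-time extraction from EMG and the RT <-> network correlation.

#' Rectified, smoothed EMG envelope
#'
#' Band-passes the trace to 1-25 Hz with a causal Butterworth filter,
#' rectifies, and smooths with a 50-ms centred moving average. The filter is
#' deliberately causal (unlike the zero-phase filter used for connectivity):
#' a zero-phase filter spreads burst energy backward in time and would bias
#' detected onsets early. Output is nonnegative and the same length as the
#' input.
#'
#' @param emg Numeric vector.
#' @param sampling_rate Sampling rate in Hz.
#' @param band Band limits in Hz for the pre-rectification filter.
#' @param smooth_seconds Moving-average window in seconds.
#' @return Numeric envelope, same length as `emg`.
#' @export
emg_envelope <- function(emg, sampling_rate, band = c(1, 25),
                         smooth_seconds = 0.05) {
  if (!length(emg)) stop("empty trace")
  nyq <- sampling_rate / 2
  if (!(band[1] > 0 && band[1] < band[2] && band[2] < nyq))
    stop("require 0 < low < high < Nyquist")
  bf <- signal::butter(4L, band / nyq, type = "pass")
  x <- abs(as.numeric(signal::filter(bf, as.numeric(emg))))
  w <- max(1L, round(smooth_seconds * sampling_rate))
  if (w %% 2L == 0L) w <- w + 1L
  sm <- stats::filter(x, rep(1 / w, w), sides = 2L)
  sm <- as.numeric(sm)
  ## moving average is undefined at the edges; hold the nearest defined value
  idx <- which(!is.na(sm))
  sm[seq_len(idx[1] - 1L)] <- sm[idx[1]]
  sm[seq.int(idx[length(idx)] + 1L, length.out = length(sm) - idx[length(idx)])] <-
    sm[idx[length(idx)]]
  pmax(sm, 0)
}

#' Detect response onset in an EMG envelope
#'
#' Onset is the first time, at or after `search_start`, where the envelope
#' exceeds `baseline mean + k * baseline SD` continuously for at least
#' `min_duration` seconds.
#'
#' @param envelope Numeric envelope (from [emg_envelope()]).
#' @param sampling_rate Sampling rate in Hz.
#' @param baseline_window `c(start, end)` in seconds, the quiet reference
#'   segment; must precede the search window.
#' @param search_start Start of the search window in seconds (defaults to
#'   the end of the baseline window).
#' @param k Threshold in baseline SDs above the baseline mean.
#' @param min_duration Minimum supra-threshold duration in seconds.
#' @return Onset time in seconds, or `NA` if the envelope never qualifies.
#' @export
detect_response_onset <- function(envelope, sampling_rate,
                                  baseline_window, search_start = NULL,
                                  k = 3, min_duration = 0.1) {
  fs <- sampling_rate
  b0 <- round(baseline_window[1] * fs) + 1L
  b1 <- round(baseline_window[2] * fs)
  if (b1 < b0) stop("empty baseline window")
  search_start <- search_start %||% baseline_window[2]
  if (search_start < baseline_window[2]) stop("baseline window must precede the search window")
  base <- envelope[b0:min(b1, length(envelope))]
  thr <- mean(base) + k * stats::sd(base)
  s0 <- round(search_start * fs) + 1L
  if (s0 > length(envelope)) return(NA_real_)
  above <- envelope[s0:length(envelope)] > thr
  need <- max(1L, round(min_duration * fs))
  run <- 0L
  for (i in seq_along(above)) {
    run <- if (above[i]) run + 1L else 0L
    if (run >= need) return((s0 - 1L + i - run) / fs)
  }
  NA_real_
}

## min-max normalization across subjects; constant input is an error
minmax01 <- function(v) {
  r <- range(v)
  if (diff(r) == 0) stop("cannot min-max normalize a constant vector")
  (v - r[1]) / diff(r)
}

#' Response time vs event-related clustering coefficient correlation
#'
#' For one condition: min-max normalizes the per-subject mean response times
#' and each ROI's per-subject event-related clustering coefficients to
#' `[0, 1]`, then runs the max-statistic Spearman permutation test of the
#' normalized RT against all ROIs jointly. The normalization is a monotone
#' map, so it leaves every Spearman correlation unchanged; it only puts the
#' reported quantities on the standard `[0, 1]` scale.
#'
#' @param behavior_table Data frame with columns `subject`, `condition`,
#'   `response_time` (trial rows are averaged per subject), or a numeric
#'   vector of per-subject mean RTs.
#' @param event_related_clustering Matrix, subjects x ROIs, of event-related
#'   clustering coefficients for the same condition.
#' @param condition Condition label selecting rows of `behavior_table`
#'   (ignored for vector input).
#' @param n_perm,seed,scheme Passed to [max_stat_spearman()].
#' @return A `permutation_result` with per-ROI Spearman rho and corrected
#'   p-values.
#' @export
rt_correlation_analysis <- function(behavior_table, event_related_clustering,
                                    condition = NULL, n_perm = 49999L, seed = 1L,
                                    scheme = "auto") {
  Yc <- as.matrix(event_related_clustering)
  if (is.data.frame(behavior_table)) {
    bt <- behavior_table
    if (!is.null(condition)) bt <- bt[bt$condition == condition, , drop = FALSE]
    rt <- tapply(bt$response_time, bt$subject, mean)
    rt <- rt[order(as.numeric(names(rt)))]
  } else rt <- as.numeric(behavior_table)
  if (length(rt) != nrow(Yc))
    stop("one mean RT per subject is required, matching the coefficient rows")
  if (length(rt) < 4L) stop("refusing correlation analysis with fewer than 4 subjects")
  x <- minmax01(rt)
  Yn <- apply(Yc, 2L, function(v) if (diff(range(v)) == 0) v else minmax01(v))
  max_stat_spearman(x, Yn, n_perm = n_perm, seed = seed, scheme = scheme)
}
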