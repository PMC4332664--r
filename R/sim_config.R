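#' Simulation configuration for the synthetic EEG study generator
#'
#' Bundles and validates every parameter of the ground-truthed generator:
#' study design (subjects, conditions, trials), the narrowband lagged-coupling
#' source model, scalp projection, artifact contamination, and the planted
#' response-time link. Defaults reproduce the emulated study design: 16
#' subjects, 25 trials per condition, 64 channels at 250 Hz, 84 cortical ROIs
#' in four equal sub-networks, upper-alpha (10-12 Hz) coupling, 2-s baseline
#' and stimulus-delivery (SDP) windows.
#'
#' @param n_subjects Number of subjects.
#' @param n_trials_per_condition Trials per subject and condition.
#' @param n_channels Number of scalp channels.
#' @param n_rois Number of cortical ROIs (sources).
#' @param sampling_rate Sampling rate in Hz.
#' @param band Two-element numeric, coupling band in Hz (upper alpha).
#' @param epoch_seconds Length of each analysis window in seconds.
#' @param partition_truth List of integer vectors: the planted sub-network
#'   membership. Must be disjoint and cover `1:n_rois`.
#' @param lag_range Two-element numeric, per-node coupling lags in seconds;
#'   both endpoints must be strictly positive (coupling is never
#'   instantaneous, so lagged phase synchronization can detect it).
#' @param coupling_within Gain of each node on its group latent.
#' @param coupling_between Baseline gain of the per-group-pair bridge latents.
#' @param planted_pairs List of 2-vectors of group indices whose between-group
#'   coupling is boosted during the SDP window of "IL" conditions.
#' @param il_boost Multiplier applied to `coupling_between` for
#'   `planted_pairs` in the SDP window of conditions matching `"-IL"`.
#' @param conditions Character vector of condition labels; labels ending in
#'   `"IL"` receive the planted SDP boost.
#' @param snr_db Source-level SNR in dB: variance of a node's narrowband
#'   signal over its 1/f background noise.
#' @param noise_max_hz Upper frequency limit of the 1/f background noise.
#'   The analysis band-passes all data to 1-30 Hz, so background power above
#'   this limit never reaches the pipeline; capping it keeps the generator's
#'   cost proportional to the band that matters. Broadband (EMG-like)
#'   contamination is modelled separately by [inject_artifacts()].
#' @param sensor_snr_db Channel-level SNR in dB applied when projecting
#'   sources to the scalp.
#' @param artifact_rates Named numeric `c(blink = , emg = )`, events per
#'   second, used by [inject_artifacts()].
#' @param rt_link List describing the planted response-time link:
#'   `roi` (target ROI index), `slope` and `noise_sd` (seconds per unit
#'   engagement and RT noise SD), `intercept` (seconds), `base_mix` (the
#'   target ROI's baseline-window coupling fraction).
#' @param stimulus_on,stimulus_off Trial timeline in seconds (fixation starts
#'   at 0; the question plays from `stimulus_on` to `stimulus_off`).
#' @param seed Integer seed; identical configurations give bit-identical
#'   simulations.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_subjects = 16L,
                       n_trials_per_condition = 25L,
                       n_channels = 64L,
                       n_rois = 84L,
                       sampling_rate = 250,
                       band = c(10, 12),
                       epoch_seconds = 2,
                       partition_truth = NULL,
                       lag_range = c(0.008, 0.040),
                       coupling_within = 1,
                       coupling_between = 0.75,
                       planted_pairs = list(c(1L, 2L), c(3L, 4L)),
                       il_boost = 2,
                       conditions = c("WE-IL", "WE-IT", "NE-IL", "NE-IT"),
                       snr_db = 5,
                       noise_max_hz = 40,
                       sensor_snr_db = 20,
                       artifact_rates = c(blink = 0.2, emg = 0.3),
                       rt_link = list(roi = 10L, slope = 0.4, noise_sd = 0.11,
                                      intercept = 0.8, base_mix = 0.3),
                       stimulus_on = 3,
                       stimulus_off = 5.5,
                       seed = 1L) {
  for (nm in c("n_subjects", "n_trials_per_condition", "n_channels", "n_rois"))
    stopifnot_scalar(get(nm), nm, positive = TRUE)
  stopifnot_scalar(sampling_rate, "sampling_rate", positive = TRUE)
  if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1])
    stop("band must be (low, high) with 0 < low < high")
  if (sampling_rate <= 2 * band[2])
    stop("sampling_rate must exceed twice the band's high edge")
  stopifnot_scalar(noise_max_hz, "noise_max_hz", positive = TRUE)
  if (noise_max_hz < band[2])
    stop("noise_max_hz must cover the coupling band")
  if (is.null(partition_truth)) {
    k <- 4L
    sizes <- rep(n_rois %/% k, k) + c(rep(1L, n_rois %% k), rep(0L, k - n_rois %% k))
    partition_truth <- split(seq_len(n_rois), rep(seq_len(k), sizes))
  }
  idx <- sort(unlist(partition_truth))
  if (!identical(as.integer(idx), seq_len(as.integer(n_rois))))
    stop("partition_truth sets must be disjoint and cover all ROIs")
  if (length(lag_range) != 2L || any(lag_range <= 0) || lag_range[2] < lag_range[1])
    stop("lag_range must be strictly positive (coupling must be non-instantaneous)")
  if (any(artifact_rates < 0)) stop("artifact_rates must be nonnegative")
  ng <- length(partition_truth)
  for (p in planted_pairs)
    if (length(p) != 2L || any(p < 1) || any(p > ng) || p[1] == p[2])
      stop("planted_pairs must be pairs of distinct group indices")
  stopifnot(is.list(rt_link), rt_link$roi >= 1, rt_link$roi <= n_rois)
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    n_trials_per_condition = as.integer(n_trials_per_condition),
    n_channels = as.integer(n_channels),
    n_rois = as.integer(n_rois),
    sampling_rate = sampling_rate,
    band = as.numeric(band),
    epoch_seconds = epoch_seconds,
    partition_truth = lapply(partition_truth, as.integer),
    lag_range = as.numeric(lag_range),
    coupling_within = coupling_within,
    coupling_between = coupling_between,
    planted_pairs = lapply(planted_pairs, as.integer),
    il_boost = il_boost,
    conditions = conditions,
    snr_db = snr_db,
    noise_max_hz = noise_max_hz,
    sensor_snr_db = sensor_snr_db,
    artifact_rates = artifact_rates,
    rt_link = rt_link,
    stimulus_on = stimulus_on,
    stimulus_off = stimulus_off,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<sim_config> %d subjects x %d conditions x %d trials; %d ROIs -> %d channels\n",
    "  band %.1f-%.1f Hz @ %g Hz, %g-s windows, snr %g dB, seed %d\n"),
    x$n_subjects, length(x$conditions), x$n_trials_per_condition,
    x$n_rois, x$n_channels, x$band[1], x$band[2], x$sampling_rate,
    x$epoch_seconds, x$snr_db, x$seed))
  invisible(x)
}
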