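## Synthetic-data generator: ground-truthed narrowband lagged-coupling sources,
## scalp projection, artifact contamination, and planted behavioral links.

complex_normal <- function(nr, nc) {
  matrix(complex(real = stats::rnorm(nr * nc), imaginary = stats::rnorm(nr * nc)),
         nr, nc) / sqrt(2)
}

## gains of the 6 per-group-pair bridge latents for one condition/window
pair_gains <- function(config, condition, window) {
  ng <- length(config$partition_truth)
  pairs <- if (ng > 1L) utils::combn(ng, 2L) else matrix(integer(0), 2L, 0L)
  b <- rep(config$coupling_between, ncol(pairs))
  if (identical(window, "sdp") && grepl("IL$", condition)) {
    for (p in config$planted_pairs) {
      j <- which(pairs[1, ] == min(p) & pairs[2, ] == max(p))
      b[j] <- b[j] * config$il_boost
    }
  }
  list(pairs = pairs, b = b)
}

## the target ROI's SDP coupling fraction as a function of subject engagement
engagement_mix <- function(e) 0.05 + 0.9 * stats::plogis(1.5 * e)

#' Ground truth of a simulated study
#'
#' Draws, deterministically from the configuration seed, every latent quantity
#' the generator plants: per-node coupling lags and gains, per-pair bridge
#' lags, the coupling-gain and analytic-coherence matrices per condition and
#' window, each subject's engagement of the target ROI, and the per-subject
#' mean response times generated from it. Downstream recovery tests compare
#' their estimates against this object.
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_ground_truth`.
#' @export
simulation_ground_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  R <- config$n_rois
  ng <- length(config$partition_truth)
  grp <- integer(R)
  for (g in seq_len(ng)) grp[config$partition_truth[[g]]] <- g
  pg <- pair_gains(config, config$conditions[1], "baseline")
  npair <- ncol(pg$pairs)

  struct <- with_seed(derive_seed(config$seed, 101L), list(
    node_lags = stats::runif(R, config$lag_range[1], config$lag_range[2]),
    node_gains = stats::runif(R, 0.8, 1.2),
    bridge_lags = matrix(stats::runif(2L * npair, config$lag_range[1],
                                      config$lag_range[2]), npair, 2L)
  ))
  engagement <- with_seed(derive_seed(config$seed, 102L),
                          stats::rnorm(config$n_subjects))

  rl <- config$rt_link
  rt <- with_seed(derive_seed(config$seed, 103L), {
    m <- matrix(NA_real_, config$n_subjects, length(config$conditions),
                dimnames = list(NULL, config$conditions))
    for (s in seq_len(config$n_subjects)) for (ci in seq_along(config$conditions)) {
      v <- rl$intercept + rl$slope * engagement[s] + stats::rnorm(1, sd = rl$noise_sd)
      ## physiological floor: a linear model with Gaussian engagement can
      ## produce non-physical means; truncate at 150 ms (simple-RT floor)
      m[s, ci] <- max(v, 0.15)
    }
    m
  })

  gain_mats <- list(); coh_mats <- list()
  for (cond in config$conditions) {
    gain_mats[[cond]] <- list(); coh_mats[[cond]] <- list()
    for (win in c("baseline", "sdp")) {
      pgc <- pair_gains(config, cond, win)
      G <- matrix(0, R, R)
      Bsum <- numeric(ng)  # total bridge power feeding each group latent
      for (j in seq_len(npair)) {
        g <- pgc$pairs[1, j]; h <- pgc$pairs[2, j]
        Bsum[g] <- Bsum[g] + pgc$b[j]^2
        Bsum[h] <- Bsum[h] + pgc$b[j]^2
      }
      C <- matrix(0, R, R)
      for (i in seq_len(R - 1L)) for (k in (i + 1L):R) {
        if (grp[i] == grp[k]) {
          G[i, k] <- config$coupling_within
          C[i, k] <- 1
        } else {
          a <- min(grp[i], grp[k]); bb <- max(grp[i], grp[k])
          j <- which(pgc$pairs[1, ] == a & pgc$pairs[2, ] == bb)
          G[i, k] <- pgc$b[j]
          C[i, k] <- pgc$b[j]^2 / sqrt((1 + Bsum[grp[i]]) * (1 + Bsum[grp[k]]))
        }
        G[k, i] <- G[i, k]; C[k, i] <- C[i, k]
      }
      gain_mats[[cond]][[win]] <- G
      coh_mats[[cond]][[win]] <- C
    }
  }

  structure(list(
    partition = grp,
    partition_sets = config$partition_truth,
    node_lags = struct$node_lags,
    node_gains = struct$node_gains,
    bridge_lags = struct$bridge_lags,
    group_pairs = pg$pairs,
    coupling_gain = gain_mats,
    coherence = coh_mats,
    planted_contrast = list(
      pairs = config$planted_pairs,
      boosted_conditions = config$conditions[grepl("IL$", config$conditions)]),
    engagement = engagement,
    target_roi = as.integer(rl$roi),
    target_mix_sdp = engagement_mix(engagement),
    target_mix_baseline = rl$base_mix,
    rt_mean = rt
  ), class = "sim_ground_truth")
}

## Generate all trials of one (subject, condition, window) as trials x ROI x time.
generate_window <- function(config, gt, subject, condition, window) {
  fs <- config$sampling_rate
  n <- round(config$epoch_seconds * fs)
  R <- config$n_rois
  Tn <- config$n_trials_per_condition
  kb <- band_bins(config$band, fs, n)
  B <- length(kb)
  f <- kb * fs / n
  grp <- gt$partition
  ng <- length(config$partition_truth)
  pgc <- pair_gains(config, condition, window)
  npair <- ncol(pgc$pairs)

  ## per-node complex weight on its group latent: gain * lag phase ramp
  PH <- exp(-2i * pi * outer(f, gt$node_lags)) *
    rep(config$coupling_within * gt$node_gains, each = B)

  ## engagement-modulated mixing for the target ROI
  tro <- gt$target_roi
  wmix <- if (identical(window, "sdp")) gt$target_mix_sdp[subject] else gt$target_mix_baseline

  ## each group latent is normalized to unit power below, so a node's signal
  ## variance -- and with it the SNR against the fixed 1/f background -- is
  ## identical across windows and conditions; only the phase-coupling
  ## structure differs. Without this, boosting a bridge gain would raise the
  ## coupled groups' signal power and leak the manipulation into
  ## within-group synchronization.
  Bsum <- numeric(ng)
  for (j in seq_len(npair)) {
    Bsum[pgc$pairs[1, j]] <- Bsum[pgc$pairs[1, j]] + pgc$b[j]^2
    Bsum[pgc$pairs[2, j]] <- Bsum[pgc$pairs[2, j]] + pgc$b[j]^2
  }
  v_sig <- (config$coupling_within * gt$node_gains)^2 * 2 * B / n^2
  v_noise <- v_sig / 10^(config$snr_db / 10)

  ## positive-frequency bins carrying background noise, capped at noise_max_hz
  nh <- min(floor((n - 1) / 2),
            max(max(kb), floor((config$noise_max_hz %||% (fs / 2)) * n / fs)))
  f_all <- seq_len(nh) * fs / n
  pk <- (1 / f_all) / sum(1 / f_all)  # 1/f background power profile
  sd_bin <- sqrt(outer(pk * n^2 / 2, v_noise))  # nh x R per-bin noise SD

  seed <- derive_seed(config$seed, 200L, subject,
                      match(condition, config$conditions),
                      if (identical(window, "sdp")) 2L else 1L)
  with_seed(seed, {
    Z <- array(complex_normal(B * ng, Tn), c(B, ng, Tn))
    W <- array(complex_normal(B * npair, Tn), c(B, npair, Tn))
    U <- Z
    for (j in seq_len(npair)) {
      g <- pgc$pairs[1, j]; h <- pgc$pairs[2, j]
      U[, g, ] <- U[, g, ] + pgc$b[j] *
        (exp(-2i * pi * f * gt$bridge_lags[j, 1]) * W[, j, ])
      U[, h, ] <- U[, h, ] + pgc$b[j] *
        (exp(-2i * pi * f * gt$bridge_lags[j, 2]) * W[, j, ])
    }
    U <- U / rep(sqrt(1 + Bsum), each = B)         # unit-power group latents
    sig <- U[, grp, , drop = FALSE] * c(PH)        # B x R x Tn
    V <- complex_normal(B, Tn)                     # target ROI private process
    sig[, tro, ] <- sqrt(wmix) * sig[, tro, ] +
      sqrt(1 - wmix) * (config$coupling_within * gt$node_gains[tro]) * V

    spec_pos <- sd_bin[, rep(seq_len(R), Tn)] * complex_normal(nh, R * Tn)
    spec_pos[kb, ] <- spec_pos[kb, ] + matrix(sig, B, R * Tn)

    full <- matrix(0i, n, R * Tn)
    full[1L + seq_len(nh), ] <- spec_pos
    full[n + 1L - seq_len(nh), ] <- Conj(spec_pos)
    x <- Re(stats::mvfft(full, inverse = TRUE)) / n   # n x (R*Tn)
    dim(x) <- c(n, R, Tn)
    aperm(x, c(3L, 2L, 1L))
  })
}

#' Simulate source-space epochs with planted coupling structure
#'
#' Generates, for one subject and condition, all trials of the baseline and
#' SDP windows as ROI source time series. Each sub-network has a latent
#' narrowband (upper-alpha) process; a node carries a lagged, gain-weighted
#' copy of its group latent plus 1/f background noise. Group pairs are coupled
#' through dedicated lagged bridge processes whose gains differ between
#' baseline and SDP per the planted condition contrast, and the target ROI's
#' coupling fraction in the SDP window follows the subject's engagement.
#'
#' @param config A [sim_config()].
#' @param subject Subject index.
#' @param condition Condition label (one of `config$conditions`).
#' @param ground_truth Optional precomputed [simulation_ground_truth()].
#' @return List with elements `baseline` and `sdp`, each a `source_epochs`
#'   object (`data` is trials x ROIs x samples), plus `ground_truth`.
#' @export
simulate_source_epochs <- function(config, subject = 1L,
                                   condition = config$conditions[1],
                                   ground_truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$band[2] >= config$sampling_rate / 2 || config$band[1] <= 0)
    stop("band outside (0, Nyquist)")
  if (!condition %in% config$conditions) stop("unknown condition: ", condition)
  gt <- ground_truth %||% simulation_ground_truth(config)
  out <- lapply(c(baseline = "baseline", sdp = "sdp"), function(win) {
    structure(list(
      data = generate_window(config, gt, subject, condition, win),
      sampling_rate = config$sampling_rate,
      window_tag = win,
      subject = subject,
      condition = condition,
      roi_labels = roi_labels_for(config$n_rois),
      band_state = "raw"
    ), class = "source_epochs")
  })
  out$ground_truth <- gt
  out
}

#' Toy leadfield: Gaussian source topographies on a spherical montage
#'
#' Electrodes sit on a fixed, deterministic upper-hemisphere lattice; sources
#' sit on a cortical shell just beneath it -- an upper-hemisphere lattice at
#' `depth` times the scalp radius, with a small seeded jitter so the geometry
#' is not perfectly regular. Keeping the sources under the electrode cap
#' mirrors the anatomy (cortical regions lie beneath the scalp montage) and
#' keeps every source resolvable; sources far outside the cap's coverage
#' would be unrecoverable by any inverse method. Each source's column is a
#' Gaussian function of electrode-source distance, centred to zero mean
#' across channels so the gain matrix is consistent with common-average
#' referencing. A stand-in for an anatomical forward model: the inverse
#' operator accepts any externally supplied leadfield.
#'
#' @param n_channels Number of electrodes (>= 2).
#' @param n_sources Number of sources (>= 1).
#' @param spread Gaussian topography width (> 0), in unit-sphere distance.
#' @param seed Integer seed for the source-position jitter.
#' @param depth Radius of the source shell relative to the scalp sphere.
#' @param jitter SD of the Gaussian positional jitter before re-projection
#'   onto the shell.
#' @return An object of class `leadfield`: list with `gain`
#'   (channels x sources, columns zero-mean), `roi_labels`,
#'   `electrode_positions`, `source_positions`.
#' @export
make_leadfield <- function(n_channels = 64L, n_sources = 84L, spread = 0.2,
                           seed = 1L, depth = 0.9, jitter = 0.03) {
  if (n_channels < 2 || n_sources < 1) stop("non-positive or degenerate dimensions")
  stopifnot_scalar(spread, "spread", positive = TRUE)
  stopifnot_scalar(depth, "depth", positive = TRUE)
  elec <- electrode_layout(n_channels)
  src <- with_seed(derive_seed(seed, 301L), {
    m <- electrode_layout(n_sources) +
      matrix(stats::rnorm(3L * n_sources, sd = jitter), n_sources, 3L)
    depth * m / sqrt(rowSums(m^2))
  })
  gain <- matrix(0, n_channels, n_sources)
  for (j in seq_len(n_sources)) {
    d2 <- rowSums((elec - matrix(src[j, ], n_channels, 3L, byrow = TRUE))^2)
    col <- exp(-d2 / (2 * spread^2))
    gain[, j] <- col - mean(col)
  }
  structure(list(gain = gain,
                 roi_labels = roi_labels_for(n_sources),
                 electrode_positions = elec,
                 source_positions = src),
            class = "leadfield")
}

roi_labels_for <- function(n) {
  if (n %% 2L == 0L) roi_labels(n) else paste0("S", seq_len(n))
}

## Deterministic Fibonacci lattice on the upper hemisphere
electrode_layout <- function(n_channels) {
  i <- seq_len(n_channels) - 0.5
  z <- i / n_channels            # upper hemisphere: z in (0, 1)
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(1 - z^2)
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Project source epochs to the scalp
#'
#' Applies the instantaneous forward model `x = G s` trial by trial and adds
#' white channel noise at the configured sensor SNR. Because the mixing is
#' instantaneous, any connectivity it creates between channels is zero-lag --
#' exactly the contamination lagged phase synchronization is built to ignore.
#'
#' @param source_epochs A `source_epochs` object.
#' @param leadfield A [make_leadfield()] result (or compatible list).
#' @param sensor_snr_db Channel-level SNR in dB; `Inf` for noiseless.
#' @param seed Integer seed for the sensor noise.
#' @return An `epoch_set` (trials x channels x samples).
#' @export
project_to_channels <- function(source_epochs, leadfield, sensor_snr_db = 20, seed = 1L) {
  G <- leadfield$gain
  d <- source_epochs$data
  Tn <- dim(d)[1]; R <- dim(d)[2]; n <- dim(d)[3]
  if (ncol(G) != R) stop("leadfield source count does not match epochs")
  S <- matrix(aperm(d, c(2L, 3L, 1L)), R, n * Tn)   # R x (n*Tn)
  X <- G %*% S
  if (is.finite(sensor_snr_db)) {
    vsig <- mean(X^2)
    X <- X + with_seed(derive_seed(seed, 302L),
                       matrix(stats::rnorm(length(X),
                                           sd = sqrt(vsig / 10^(sensor_snr_db / 10))),
                              nrow(X)))
  }
  dim(X) <- c(nrow(G), n, Tn)
  structure(list(
    data = aperm(X, c(3L, 1L, 2L)),
    sampling_rate = source_epochs$sampling_rate,
    window_tag = source_epochs$window_tag,
    subject = source_epochs$subject,
    condition = source_epochs$condition,
    channel_labels = paste0("ch", seq_len(nrow(G))),
    band_state = "raw"
  ), class = "epoch_set")
}

#' Contaminate scalp epochs with ocular and myogenic artifacts
#'
#' Adds blink-like transients (slow, < 4 Hz, frontally weighted bumps) and
#' EMG-like bursts (broadband noise with low lag-1 autocorrelation, localized
#' in time and laterally weighted in space) at the configured Poisson rates,
#' and returns dedicated EOG and EMG reference channels carrying the injected
#' waveforms plus a small amount of measurement noise.
#'
#' @param epochs An `epoch_set` (trials x channels x samples).
#' @param config A [sim_config()]; `artifact_rates` gives events per second.
#' @param seed Integer seed.
#' @return List: `epochs` (contaminated `epoch_set`), `eog` and `emg`
#'   (trials x samples reference channels), `events` (data frame of injected
#'   artifact times).
#' @export
inject_artifacts <- function(epochs, config, seed = 1L) {
  d <- epochs$data
  Tn <- dim(d)[1]; C <- dim(d)[2]; n <- dim(d)[3]
  fs <- epochs$sampling_rate
  rates <- config$artifact_rates
  eog <- matrix(0, Tn, n); emg <- matrix(0, Tn, n)
  if (all(rates <= 0)) {
    return(list(epochs = epochs, eog = eog, emg = emg,
                events = data.frame(trial = integer(), type = character(),
                                    time = numeric())))
  }
  elec <- electrode_layout(C)
  ## frontal weighting for blinks; lateral (temporal) for EMG
  front <- exp(-rowSums((elec - matrix(c(0, 0.95, 0.31), C, 3L, byrow = TRUE))^2) / 0.3)
  rms <- sqrt(mean(d^2))
  ev <- list()
  out <- with_seed(derive_seed(seed, 303L), {
    for (tr in seq_len(Tn)) {
      nb <- stats::rpois(1, rates[["blink"]] * n / fs)
      for (b in seq_len(nb)) {
        dur <- round(0.35 * fs)
        t0 <- sample.int(max(n - dur, 1L), 1L)
        idx <- t0:min(t0 + dur - 1L, n)
        bump <- (sin(pi * seq_along(idx) / length(idx)))^2 * 8 * rms
        d[tr, , idx] <- d[tr, , idx] + outer(front, bump)
        eog[tr, idx] <- eog[tr, idx] + bump
        ev[[length(ev) + 1L]] <- data.frame(trial = tr, type = "blink", time = t0 / fs)
      }
      ne <- stats::rpois(1, rates[["emg"]] * n / fs)
      for (b in seq_len(ne)) {
        dur <- round(stats::runif(1, 0.2, 0.5) * fs)
        t0 <- sample.int(max(n - dur, 1L), 1L)
        idx <- t0:min(t0 + dur - 1L, n)
        env <- sin(pi * seq_along(idx) / length(idx))
        wav <- stats::rnorm(length(idx)) * env * 3 * rms
        ctr <- sample.int(C, 1L)
        topo <- exp(-rowSums((elec - matrix(elec[ctr, ], C, 3L, byrow = TRUE))^2) / 0.2)
        d[tr, , idx] <- d[tr, , idx] + outer(topo, wav)
        emg[tr, idx] <- emg[tr, idx] + wav
        ev[[length(ev) + 1L]] <- data.frame(trial = tr, type = "emg", time = t0 / fs)
      }
    }
    sd_ref <- 0.02 * max(rms, 1e-12)
    eog <- eog + matrix(stats::rnorm(Tn * n, sd = sd_ref), Tn, n)
    emg <- emg + matrix(stats::rnorm(Tn * n, sd = sd_ref), Tn, n)
    list(d = d, eog = eog, emg = emg)
  })
  epochs$data <- out$d
  list(epochs = epochs, eog = out$eog, emg = out$emg,
       events = if (length(ev)) do.call(rbind, ev)
                else data.frame(trial = integer(), type = character(), time = numeric()))
}

#' Simulate behavioral responses (response times and EMG traces)
#'
#' Per subject and condition, the mean response time is
#' `intercept + slope * engagement + noise` (drawn in
#' [simulation_ground_truth()]); trial-level response times jitter around that
#' mean and are redrawn while nonpositive. Optionally emits, per trial, a
#' synthetic rectifiable EMG trace whose burst starts `RT` seconds after
#' stimulus offset, for exercising the response-onset detector.
#'
#' @param ground_truth A [simulation_ground_truth()].
#' @param config The matching [sim_config()].
#' @param emg_traces If `TRUE`, attach per-trial EMG traces.
#' @param trial_sd SD of the trial-level RT jitter (s).
#' @return List: `table` (data frame subject/condition/trial/response_time),
#'   `subject_means` (subjects x conditions matrix), and if requested
#'   `traces` (list of numeric vectors) aligned with `table` rows plus
#'   `trace_fs` and `stimulus_off`.
#' @export
simulate_behavior <- function(ground_truth, config, emg_traces = FALSE,
                              trial_sd = 0.05) {
  gt <- ground_truth
  fs <- config$sampling_rate
  rows <- list(); traces <- list()
  with_seed(derive_seed(config$seed, 304L), {
    for (s in seq_len(config$n_subjects)) for (cond in config$conditions) {
      mu <- gt$rt_mean[s, cond]
      for (tr in seq_len(config$n_trials_per_condition)) {
        rt <- NA_real_
        for (k in seq_len(100L)) {
          v <- mu + stats::rnorm(1, sd = trial_sd)
          if (v > 0) { rt <- v; break }
        }
        if (is.na(rt)) stop("failed to draw a positive response time in 100 attempts")
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s, condition = cond, trial = tr, response_time = rt)
        if (emg_traces) {
          onset <- config$stimulus_off + rt
          len <- round((onset + 0.7) * fs)
          tr_sig <- stats::rnorm(len, sd = 0.02)
          i0 <- round(onset * fs) + 1L
          idx <- i0:len
          tt <- seq_along(idx) / fs
          tr_sig[idx] <- tr_sig[idx] +
            sin(2 * pi * 15 * tt) * (1 - exp(-tt / 0.03))  # 1-25 Hz band content
          traces[[length(traces) + 1L]] <- tr_sig
        }
      }
    }
  })
  out <- list(table = do.call(rbind, rows), subject_means = gt$rt_mean)
  if (emg_traces) {
    out$traces <- traces
    out$trace_fs <- fs
    out$stimulus_off <- config$stimulus_off
  }
  out
}

#' Analytic lagged phase synchronization of a pure delay
#'
#' Closed-form prediction for the generator's latent-delay model: two
#' noiseless nodes carrying the same band-limited latent with a relative
#' delay `delta_lag` have per-bin phase difference `-2*pi*f*delta_lag`;
#' averaging the unit phasors over the band bins of a `n_samples`-sample
#' epoch gives the population coherency, from which LPS follows as
#' `Im(rho)^2 / (1 - Re(rho)^2)`.
#'
#' @param delta_lag Relative delay in seconds (lag of node 1 minus node 2).
#' @param band Band limits in Hz.
#' @param sampling_rate Sampling rate in Hz.
#' @param n_samples Epoch length in samples.
#' @return The analytic LPS value in `[0, 1]`.
#' @export
analytic_lps_delay <- function(delta_lag, band = c(10, 12), sampling_rate = 250,
                               n_samples = 500) {
  k <- band_bins(band, sampling_rate, n_samples)
  f <- k * sampling_rate / n_samples
  rho <- mean(exp(-2i * pi * f * delta_lag))
  lps_from_rho(rho)
}

## LPS of a complex coherency value (shared with the connectivity module)
lps_from_rho <- function(rho, tol = 1e-12) {
  den <- 1 - Re(rho)^2
  out <- ifelse(den < tol, 0, Im(rho)^2 / den)
  pmin(pmax(out, 0), 1)
}
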