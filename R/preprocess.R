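## Cleaning chain: zero-phase band-pass, common-average reference, epoching,
## SOBI-based EOG removal, BSS-CCA EMG removal, trial rejection.

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth band-pass applied forward and backward
#' (`signal::filtfilt`), so the net response is 8th order with zero phase --
#' phase distortion would corrupt lagged-phase-synchronization estimates
#' downstream. Attenuation one octave outside the band exceeds 40 dB; the
#' passband is monotone (no ripple).
#'
#' @param x Numeric vector, matrix with one signal per row, 3-D array
#'   (trials x channels x samples), or an `epoch_set`/`source_epochs` object.
#' @param low_hz,high_hz Band edges in Hz, `0 < low < high < Nyquist`.
#' @param sampling_rate Sampling rate in Hz (taken from the object when `x`
#'   is an epoch container).
#' @param order Butterworth order per pass.
#' @return Same shape/class as the input, filtered; epoch containers get
#'   `band_state = "filtered"`.
#' @export
bandpass_filter <- function(x, low_hz, high_hz, sampling_rate = NULL, order = 4L) {
  if (is.list(x) && !is.null(x$data)) {
    fs <- sampling_rate %||% x$sampling_rate
    x$data <- bandpass_filter(x$data, low_hz, high_hz, fs, order)
    x$band_state <- "filtered"
    return(x)
  }
  fs <- sampling_rate
  if (is.null(fs)) stop("sampling_rate is required for raw numeric input")
  nyq <- fs / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop("require 0 < low_hz < high_hz < Nyquist")
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  ff <- function(v) signal::filtfilt(bf, v)
  if (is.null(dim(x))) return(ff(as.numeric(x)))
  if (length(dim(x)) == 2L) return(t(apply(x, 1L, ff)))
  if (length(dim(x)) == 3L) {
    out <- x
    for (tr in seq_len(dim(x)[1])) out[tr, , ] <- t(apply(x[tr, , , drop = TRUE], 1L, ff))
    return(out)
  }
  stop("unsupported input shape")
}

#' Re-reference to the common average
#'
#' Subtracts, at every sample, the instantaneous mean across channels, so the
#' channel mean is identically zero afterwards. Idempotent and linear.
#'
#' @param x Matrix (channels x samples), 3-D array (trials x channels x
#'   samples), or `epoch_set`.
#' @return Input with zero channel mean at every sample.
#' @export
rereference_common_average <- function(x) {
  if (is.list(x) && !is.null(x$data)) {
    x$data <- rereference_common_average(x$data)
    return(x)
  }
  if (length(dim(x)) == 2L) {
    if (nrow(x) < 2L) stop("common-average reference needs >= 2 channels")
    return(sweep(x, 2L, colMeans(x)))
  }
  if (length(dim(x)) == 3L) {
    if (dim(x)[2] < 2L) stop("common-average reference needs >= 2 channels")
    m <- apply(x, c(1L, 3L), mean)        # trials x samples
    return(x - aperm(array(m, c(dim(x)[1], dim(x)[3], dim(x)[2])), c(1L, 3L, 2L)))
  }
  stop("unsupported input shape")
}

## Approximate joint diagonalization of symmetric matrices by Givens sweeps
## (Cardoso & Souloumiac). M: p x p x K array. Returns orthogonal V and the
## off-diagonal objective per sweep.
joint_diagonalize <- function(M, tol = 1e-8, max_sweeps = 100L) {
  p <- dim(M)[1]; K <- dim(M)[3]
  V <- diag(p)
  offcrit <- function() {
    s <- 0
    for (k in seq_len(K)) { A <- M[, , k]; s <- s + sum(A^2) - sum(diag(A)^2) }
    s
  }
  objective <- numeric(0)
  for (sweep in seq_len(max_sweeps)) {
    changed <- FALSE
    for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
      g1 <- M[i, i, ] - M[j, j, ]
      g2 <- M[i, j, ] + M[j, i, ]
      gg11 <- sum(g1 * g1); gg12 <- sum(g1 * g2); gg22 <- sum(g2 * g2)
      ton <- gg11 - gg22; toff <- 2 * gg12
      theta <- 0.5 * atan2(toff, ton + sqrt(ton^2 + toff^2))
      cs <- cos(theta); sn <- sin(theta)
      if (abs(sn) > tol) {
        changed <- TRUE
        Mi <- M[i, , ]; Mj <- M[j, , ]          # p x K slabs
        M[i, , ] <- cs * Mi + sn * Mj
        M[j, , ] <- -sn * Mi + cs * Mj
        Mi <- M[, i, ]; Mj <- M[, j, ]
        M[, i, ] <- cs * Mi + sn * Mj
        M[, j, ] <- -sn * Mi + cs * Mj
        Vi <- V[, i]; Vj <- V[, j]
        V[, i] <- cs * Vi + sn * Vj
        V[, j] <- -sn * Vi + cs * Vj
      }
    }
    objective <- c(objective, offcrit())
    if (!changed) break
    if (sweep > 1L &&
        abs(objective[sweep - 1L] - objective[sweep]) <
          tol * max(objective[1L], .Machine$double.eps)) break
  }
  list(V = V, objective = objective)
}

#' Second-order blind identification (SOBI)
#'
#' Whitens the data, builds time-lagged covariance matrices at the requested
#' lags (symmetrized), and approximately joint-diagonalizes them with
#' iterative Givens rotations. Sources with distinct autocovariance
#' structure are separated; the decomposition is deterministic.
#'
#' @param data Matrix, channels x samples (samples should greatly exceed
#'   channels).
#' @param lags Integer vector of positive lags in samples.
#' @param tol Convergence tolerance of the joint-diagonalization sweeps.
#' @param rank_tol Relative eigenvalue cutoff below which the whitening stage
#'   drops dimensions (rank-deficient input triggers a warning).
#' @return List: `mixing` (channels x m), `unmixing` (m x channels),
#'   `sources` (m x samples), `objective` (off-diagonal criterion per sweep,
#'   non-increasing).
#' @export
sobi_decompose <- function(data, lags = 1:50, tol = 1e-8, rank_tol = 1e-10) {
  stopifnot(is.matrix(data), length(lags) >= 1L, all(lags >= 1L))
  p <- nrow(data); n <- ncol(data)
  if (n <= p) stop("need more samples than channels")
  X <- data - rowMeans(data)
  C0 <- tcrossprod(X) / n
  eg <- eigen(C0, symmetric = TRUE)
  keep <- eg$values > rank_tol * max(eg$values)
  m <- sum(keep)
  if (m < p) warning(sprintf("rank-deficient covariance: reducing %d -> %d dimensions", p, m))
  E <- eg$vectors[, seq_len(m), drop = FALSE]
  dv <- eg$values[seq_len(m)]
  Q <- diag(1 / sqrt(dv), m) %*% t(E)       # whitener, m x p
  Y <- Q %*% X
  lags <- lags[lags < n]
  M <- array(0, c(m, m, length(lags)))
  for (k in seq_along(lags)) {
    l <- lags[k]
    Cl <- Y[, 1:(n - l), drop = FALSE] %*% t(Y[, (1 + l):n, drop = FALSE]) / (n - l)
    M[, , k] <- (Cl + t(Cl)) / 2
  }
  jd <- joint_diagonalize(M, tol = tol)
  V <- jd$V
  W <- t(V) %*% Q                            # unmixing, m x p
  A <- E %*% diag(sqrt(dv), m) %*% V         # mixing, p x m
  list(mixing = A, unmixing = W, sources = W %*% X, objective = jd$objective)
}

#' Remove EOG-correlated SOBI components
#'
#' Decomposes each trial with SOBI, zeroes every component whose absolute
#' correlation with the EOG reference channel reaches the threshold, and
#' reconstructs the trial from the remaining components. Trials where no
#' component reaches the threshold are returned unchanged (optionally, the
#' single most-correlated component can be removed instead).
#'
#' @param epochs An `epoch_set` (trials x channels x samples).
#' @param eog_channel Matrix, trials x samples, the EOG reference.
#' @param threshold Absolute-correlation threshold in `[0, 1]` (values above
#'   1 are unreachable: nothing is ever removed).
#' @param fallback_most_correlated If `TRUE`, remove the most-correlated
#'   component when none reaches the threshold.
#' @param lags SOBI lag set.
#' @return The cleaned `epoch_set`; attribute `"notices"` lists trials where
#'   nothing was removed, attribute `"removed"` the per-trial component count.
#' @export
remove_eog_components <- function(epochs, eog_channel, threshold = 0.7,
                                  fallback_most_correlated = FALSE, lags = 1:50) {
  d <- epochs$data
  Tn <- dim(d)[1]
  stopifnot(is.matrix(eog_channel), nrow(eog_channel) == Tn,
            ncol(eog_channel) == dim(d)[3])
  notices <- character(0); removed <- integer(Tn)
  for (tr in seq_len(Tn)) {
    X <- d[tr, , , drop = TRUE]
    dec <- sobi_decompose(X, lags = lags)
    r <- suppressWarnings(abs(apply(dec$sources, 1L, stats::cor, y = eog_channel[tr, ])))
    r[is.na(r)] <- 0
    drop_idx <- which(r >= threshold)
    if (!length(drop_idx)) {
      if (fallback_most_correlated) {
        drop_idx <- which.max(r)
      } else {
        notices <- c(notices, sprintf("trial %d: no component reached threshold %.3g; unchanged",
                                      tr, threshold))
        next
      }
    }
    keep <- setdiff(seq_len(nrow(dec$sources)), drop_idx)
    d[tr, , ] <- dec$mixing[, keep, drop = FALSE] %*%
      dec$sources[keep, , drop = FALSE] + rowMeans(X)
    removed[tr] <- length(drop_idx)
  }
  epochs$data <- d
  attr(epochs, "notices") <- notices
  attr(epochs, "removed") <- removed
  epochs
}

#' Remove low-autocorrelation components (BSS-CCA EMG removal)
#'
#' Blind source separation against a one-sample-delayed copy of the data:
#' after whitening, the components are the eigenvectors of the symmetrized
#' lag-1 covariance, ordered by canonical correlation (equal to each
#' component's lag-1 autocorrelation). Broadband myogenic activity has low
#' lag-1 autocorrelation while band-limited cortical activity has high
#' autocorrelation, so components below the threshold are discarded and the
#' trial reconstructed from the rest.
#'
#' @param epochs An `epoch_set` (trials x channels x samples).
#' @param autocorr_threshold Components with lag-1 autocorrelation below this
#'   value are removed; must lie in (0, 1).
#' @return The cleaned `epoch_set`; attribute `"removed"` gives per-trial
#'   removed-component counts, `"autocorrelations"` the per-trial spectra.
#' @export
bsscca_remove_emg <- function(epochs, autocorr_threshold = 0.85) {
  if (!(autocorr_threshold > 0 && autocorr_threshold < 1))
    stop("autocorr_threshold must lie in (0, 1)")
  d <- epochs$data
  Tn <- dim(d)[1]
  if (dim(d)[3] < 2L) stop("epochs must have >= 2 samples")
  removed <- integer(Tn); acs <- vector("list", Tn)
  for (tr in seq_len(Tn)) {
    X <- d[tr, , , drop = TRUE]
    mu <- rowMeans(X)
    Xc <- X - mu
    n <- ncol(Xc)
    C0 <- tcrossprod(Xc) / n
    eg <- eigen(C0, symmetric = TRUE)
    keepdim <- eg$values > 1e-10 * max(eg$values)
    E <- eg$vectors[, keepdim, drop = FALSE]
    dv <- eg$values[keepdim]
    Q <- diag(1 / sqrt(dv), length(dv)) %*% t(E)
    Y <- Q %*% Xc
    C1 <- Y[, 1:(n - 1), drop = FALSE] %*% t(Y[, 2:n, drop = FALSE]) / (n - 1)
    C1 <- (C1 + t(C1)) / 2
    eg1 <- eigen(C1, symmetric = TRUE)      # eigenvalues = lag-1 autocorrelations
    ac <- eg1$values
    acs[[tr]] <- ac
    keep <- ac >= autocorr_threshold
    removed[tr] <- sum(!keep)
    if (any(!keep)) {
      V <- eg1$vectors
      A <- E %*% diag(sqrt(dv), length(dv)) %*% V
      S <- t(V) %*% Y
      d[tr, , ] <- A[, keep, drop = FALSE] %*% S[keep, , drop = FALSE] + mu
    }
  }
  epochs$data <- d
  attr(epochs, "removed") <- removed
  attr(epochs, "autocorrelations") <- acs
  epochs
}

#' Extract baseline and SDP epochs from a continuous recording
#'
#' For every `stimulus_on` event, cuts the last 2 s of the preceding fixation
#' (baseline) and the first 2 s of the stimulus delivery period (SDP).
#' Trials whose windows fall outside the recording are dropped and logged.
#'
#' @param recording List with `samples` (channels x time matrix),
#'   `sampling_rate`, and `events` (data frame with columns `time` in seconds
#'   and `label`).
#' @param window_spec List with `baseline` and `sdp`, each `c(start, end)` in
#'   seconds relative to stimulus onset. Default: baseline `[-2, 0)`,
#'   SDP `[0, 2)`.
#' @return List: `baseline` and `sdp` (`epoch_set`s), `dropped` (data frame
#'   of dropped trials and reasons).
#' @export
extract_epochs <- function(recording,
                           window_spec = list(baseline = c(-2, 0), sdp = c(0, 2))) {
  fs <- recording$sampling_rate
  X <- recording$samples
  ntot <- ncol(X)
  ev <- recording$events
  onsets <- ev$time[ev$label == "stimulus_on"]
  if (!length(onsets)) stop("no stimulus_on events in recording")
  if (any(diff(ev$time) <= 0)) stop("events must be strictly increasing in time")
  nsamp <- vapply(window_spec, function(w) round((w[2] - w[1]) * fs), numeric(1))
  keep <- list(); dropped <- list()
  for (i in seq_along(onsets)) {
    segs <- lapply(window_spec, function(w) {
      i0 <- round((onsets[i] + w[1]) * fs) + 1L
      i1 <- i0 + round((w[2] - w[1]) * fs) - 1L
      c(i0, i1)
    })
    bad <- vapply(segs, function(s) s[1] < 1L || s[2] > ntot, logical(1))
    if (any(bad)) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(trial = i, reason = "window outside recording")
      next
    }
    keep[[length(keep) + 1L]] <- list(trial = i, segs = segs)
  }
  make_set <- function(win) {
    arr <- array(NA_real_, c(length(keep), nrow(X), nsamp[[win]]))
    for (j in seq_along(keep)) {
      s <- keep[[j]]$segs[[win]]
      arr[j, , ] <- X[, s[1]:s[2]]
    }
    structure(list(data = arr, sampling_rate = fs, window_tag = win,
                   trial_index = vapply(keep, `[[`, numeric(1), "trial"),
                   channel_labels = rownames(X) %||% paste0("ch", seq_len(nrow(X))),
                   band_state = "raw"),
              class = "epoch_set")
  }
  list(baseline = make_set("baseline"), sdp = make_set("sdp"),
       dropped = if (length(dropped)) do.call(rbind, dropped)
                 else data.frame(trial = integer(), reason = character()))
}

#' Reject residually noisy trials
#'
#' Drops trials whose root-mean-square amplitude exceeds a multiple of the
#' median trial RMS -- the final screen for trials that survive artifact
#' removal still visibly contaminated.
#'
#' @param epochs An `epoch_set`.
#' @param rms_factor Rejection threshold as a multiple of the median RMS.
#' @return The `epoch_set` with noisy trials removed; attribute `"rejected"`
#'   lists their indices.
#' @export
reject_noisy_trials <- function(epochs, rms_factor = 3) {
  d <- epochs$data
  rms <- sqrt(apply(d^2, 1L, mean))
  bad <- which(rms > rms_factor * stats::median(rms))
  if (length(bad)) epochs$data <- d[-bad, , , drop = FALSE]
  attr(epochs, "rejected") <- bad
  epochs
}
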