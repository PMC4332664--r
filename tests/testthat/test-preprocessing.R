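test_that("band-pass filter keeps the band and kills what is outside it", {
  fs <- 250; n <- 2500
  t <- seq_len(n) / fs
  keep <- sin(2 * pi * 10 * t)
  low <- sin(2 * pi * 0.3 * t)
  high <- sin(2 * pi * 60 * t)
  y <- bandpass_filter(keep + low + high, 1, 30, fs)
  mid <- 500:2000  # avoid filter edge transients
  ## the 10 Hz component survives nearly unchanged
  expect_gt(cor(y[mid], keep[mid]), 0.99)
  expect_equal(sd(y[mid]), sd(keep[mid]), tolerance = 0.05)
  ## out-of-band residual is tiny
  expect_lt(sd((y - keep)[mid]), 0.05 * sd(keep[mid]))
  expect_error(bandpass_filter(keep, 30, 1, fs), "low_hz")
  expect_error(bandpass_filter(keep, 1, 30), "sampling_rate")
})

test_that("band-pass filter is zero-phase", {
  fs <- 250; t <- seq_len(2500) / fs
  x <- sin(2 * pi * 11 * t)
  y <- bandpass_filter(x, 8, 14, fs)
  mid <- 500:2000
  cc <- sapply(-3:3, function(l) cor(x[mid], y[mid + l]))
  expect_equal(which.max(cc), 4L)  # zero lag maximizes the cross-correlation
})

test_that("common-average reference zeroes the channel mean and is idempotent", {
  set.seed(1)
  x <- matrix(rnorm(8 * 100), 8, 100) + 5
  y <- rereference_common_average(x)
  expect_lt(max(abs(colMeans(y))), 1e-12)
  expect_equal(rereference_common_average(y), y, tolerance = 1e-12)
  a <- array(rnorm(3 * 4 * 50), c(3, 4, 50))
  b <- rereference_common_average(a)
  expect_lt(max(abs(apply(b, c(1, 3), mean))), 1e-12)
  expect_error(rereference_common_average(matrix(1, 1, 10)), ">= 2 channels")
})

test_that("SOBI separates AR sources with distinct spectra", {
  set.seed(42)
  n <- 4000
  phis <- c(0.9, 0.5, -0.5, 0.1)
  S <- t(sapply(phis, function(ph) as.numeric(arima.sim(list(ar = ph), n))))
  S <- S / sqrt(rowSums(S^2) / n)
  A <- matrix(rnorm(16), 4, 4)
  X <- A %*% S
  dec <- sobi_decompose(X, lags = 1:20)
  expect_lt(amari_index(dec$unmixing, A), 0.1)
  ## mixing and unmixing are mutually inverse on the kept subspace
  expect_equal(dec$unmixing %*% dec$mixing, diag(4), tolerance = 1e-6)
  ## objective is non-increasing
  expect_true(all(diff(dec$objective) <= 1e-8))
})

test_that("joint diagonalization solves an exactly diagonalizable set", {
  set.seed(3)
  V0 <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
  M <- array(0, c(5, 5, 3))
  for (k in 1:3) M[, , k] <- V0 %*% diag(rnorm(5)) %*% t(V0)
  jd <- lpsnet:::joint_diagonalize(M)
  ## V'MV diagonal for every slab
  for (k in 1:3) {
    D <- t(jd$V) %*% M[, , k] %*% jd$V
    expect_lt(max(abs(D - diag(diag(D)))), 1e-6)
  }
})

test_that("SOBI-based EOG removal subtracts a planted blink component", {
  set.seed(7)
  fs <- 250; n <- 500; Tn <- 4; C <- 6
  t <- seq_len(n) / fs
  d <- array(0, c(Tn, C, n)); eog <- matrix(0, Tn, n)
  topo <- c(3, 2, 1, 0.5, 0.2, 0.1)
  for (tr in seq_len(Tn)) {
    brain <- t(sapply(1:C, function(i)
      sin(2 * pi * (8 + i) * t + tr) + 0.3 * rnorm(n)))
    blink <- exp(-(t - 1)^2 / 0.02) * 8
    d[tr, , ] <- brain + outer(topo, blink)
    eog[tr, ] <- blink + rnorm(n, sd = 0.05)
  }
  ep <- structure(list(data = d, sampling_rate = fs), class = "epoch_set")
  cl <- remove_eog_components(ep, eog, threshold = 0.7)
  expect_true(all(attr(cl, "removed") >= 1))
  for (tr in seq_len(Tn)) {
    before <- max(abs(cor(t(d[tr, , ]), eog[tr, ])))
    after <- max(abs(cor(t(cl$data[tr, , ]), eog[tr, ])))
    expect_lt(after, 0.3)
    expect_gt(before, 0.9)
  }
  ## unreachable threshold leaves data untouched and says so
  un <- remove_eog_components(ep, eog, threshold = 1.5)
  expect_identical(un$data, ep$data)
  expect_length(attr(un, "notices"), Tn)
})

test_that("BSS-CCA removes broadband low-autocorrelation contamination", {
  set.seed(11)
  fs <- 250; n <- 500; C <- 6
  t <- seq_len(n) / fs
  brain <- t(sapply(1:C, function(i) sin(2 * pi * (9 + 0.5 * i) * t + i)))
  emg_src <- rnorm(n)                       # white: lag-1 autocorrelation ~ 0
  topo <- c(0.1, 0.1, 0.2, 0.5, 2, 3)
  X <- brain + outer(topo, emg_src)
  ep <- structure(list(data = array(X, c(1, C, n)), sampling_rate = fs),
                  class = "epoch_set")
  cl <- bsscca_remove_emg(ep, autocorr_threshold = 0.85)
  expect_gte(attr(cl, "removed")[1], 1)
  resid_before <- X - brain
  resid_after <- cl$data[1, , ] - brain
  expect_lt(sum(resid_after^2), 0.1 * sum(resid_before^2))
  ## clean narrowband data passes through essentially unchanged
  ep2 <- structure(list(data = array(brain, c(1, C, n)), sampling_rate = fs),
                  class = "epoch_set")
  cl2 <- bsscca_remove_emg(ep2, autocorr_threshold = 0.85)
  expect_equal(cl2$data[1, , ], brain, tolerance = 0.05)
  expect_error(bsscca_remove_emg(ep, autocorr_threshold = 1.2), "autocorr_threshold")
})

test_that("epoch extraction cuts the documented windows and drops bad trials", {
  fs <- 100
  X <- matrix(seq_len(2 * 3000), nrow = 2, byrow = TRUE)  # 30 s, 2 channels
  ev <- data.frame(time = c(1.0, 5.0, 10.0, 29.5),
                   label = c("stimulus_on", "stimulus_on", "stimulus_on", "stimulus_on"))
  out <- extract_epochs(list(samples = X, sampling_rate = fs, events = ev))
  ## trial 1 has no full 2-s baseline, trial 4 no full SDP: both dropped
  expect_equal(nrow(out$dropped), 2)
  expect_equal(dim(out$baseline$data), c(2, 2, 200))
  expect_equal(dim(out$sdp$data), c(2, 2, 200))
  ## SDP window of the 5-s onset starts exactly at sample 501
  expect_equal(out$sdp$data[1, 1, 1], X[1, 501])
  expect_equal(out$baseline$data[1, 1, 1], X[1, 301])
})

test_that("trial rejection drops only outlier-RMS trials", {
  set.seed(2)
  d <- array(rnorm(10 * 4 * 100), c(10, 4, 100))
  d[3, , ] <- d[3, , ] * 50
  ep <- structure(list(data = d, sampling_rate = 100), class = "epoch_set")
  out <- reject_noisy_trials(ep, rms_factor = 3)
  expect_equal(attr(out, "rejected"), 3L)
  expect_equal(dim(out$data)[1], 9)
})
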