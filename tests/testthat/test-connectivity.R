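test_that("LPS formula oracle values are exact", {
  rho <- matrix(c(1, 0.5 + 0.5i, 0.5 - 0.5i, 1), 2, 2)
  expect_equal(lagged_phase_synchronization(rho)$values[1, 2], 1 / 3)
  rho <- matrix(c(1, 1i, -1i, 1), 2, 2)
  expect_equal(lagged_phase_synchronization(rho)$values[1, 2], 1)
  ## degenerate purely instantaneous case maps to 0 by convention
  rho <- matrix(c(1, 1, 1, 1), 2, 2) + 0i
  expect_equal(lagged_phase_synchronization(rho)$values[1, 2], 0)
})

test_that("LPS output is a symmetric zero-diagonal matrix in [0, 1]", {
  set.seed(1)
  z <- matrix(complex(real = rnorm(16), imaginary = rnorm(16)), 4, 4)
  rho <- z %*% Conj(t(z))
  rho <- rho / sqrt(outer(Re(diag(rho)), Re(diag(rho))))  # normalized coherency
  v <- lagged_phase_synchronization(rho)$values
  expect_equal(v, t(v))
  expect_equal(diag(v), rep(0, 4))
  expect_true(all(v >= 0 & v <= 1))
  ## integrity guard on impossible coherencies
  bad <- matrix(c(1, 2 + 0i, 2 + 0i, 1), 2, 2)
  expect_error(lagged_phase_synchronization(bad), "integrity")
})

test_that("band cross-spectra match the naive reference implementation", {
  set.seed(9)
  d <- array(rnorm(6 * 4 * 250), c(6, 4, 250))
  cs <- band_cross_spectra(d, band = c(10, 12), sampling_rate = 125)
  bins <- lpsnet:::band_bins(c(10, 12), 125, 250)
  ref <- naive_band_rho(d, bins)
  diag(ref) <- 1
  expect_equal(cs$rho, ref, tolerance = 1e-10)
  expect_equal(diag(cs$rho), rep(1 + 0i, 4))
  expect_equal(cs$n_bins, length(bins))
  expect_error(band_cross_spectra(d, band = c(60, 70), sampling_rate = 125),
               "Nyquist")
  expect_error(band_cross_spectra(d[1, , , drop = FALSE], band = c(10, 12),
                                  sampling_rate = 125), "2 trials")
})

test_that("a delayed narrowband pair yields high LPS, an instantaneous pair none", {
  fs <- 250; n <- 500; Tn <- 40
  t <- seq_len(n) / fs
  set.seed(12)
  d <- array(0, c(Tn, 3, n))
  for (tr in seq_len(Tn)) {
    ph <- runif(1, 0, 2 * pi)
    base <- sin(2 * pi * 11 * t + ph)
    d[tr, 1, ] <- base + 0.2 * rnorm(n)
    d[tr, 2, ] <- sin(2 * pi * 11 * (t - 0.02) + ph) + 0.2 * rnorm(n)  # 20 ms lag
    d[tr, 3, ] <- base + 0.2 * rnorm(n)                                # zero lag
  }
  ## evaluate at the sinusoid's own bin (11 Hz); averaging over a wider band
  ## would dilute a single-frequency signal with noise-only bins
  v <- lagged_phase_synchronization(band_cross_spectra(d, c(10.8, 11.2), fs))$values
  expect_gt(v[1, 2], 0.9)
  expect_lt(v[1, 3], 0.05)
})

test_that("event-related index has the documented contract", {
  mk <- function(vals) structure(list(values = vals, normalization = "absolute",
                                      band = c(10, 12)), class = "connectivity_matrix")
  ev <- mk(matrix(c(0, 0.3, 0.3, 0), 2, 2))
  bl <- mk(matrix(c(0, 0.2, 0.2, 0), 2, 2))
  c1 <- event_related_index(ev, bl)
  expect_equal(c1$values[1, 2], 0.5)  # (0.3 - 0.2) / 0.2
  expect_equal(c1$normalization, "event_related")
  ## ratio variant
  expect_equal(event_related_index(ev, bl, ratio = TRUE)$values[1, 2], 1.5)
  ## floored entries are flagged
  bl0 <- mk(matrix(0, 2, 2))
  fl <- event_related_index(ev, bl0)
  expect_equal(nrow(attr(fl, "floored")), 1)
  ## contract violations
  blb <- mk(matrix(c(0, 0.2, 0.2, 0), 2, 2)); blb$band <- c(8, 10)
  expect_error(event_related_index(ev, blb), "band")
  evr <- c1
  expect_error(event_related_index(evr, bl), "absolute")
})
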