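test_that("simulation is deterministic given the seed", {
  cfg <- tiny_config(seed = 9L)
  a <- simulate_source_epochs(cfg, 2, "WE-IL")
  b <- simulate_source_epochs(cfg, 2, "WE-IL")
  expect_identical(a$sdp$data, b$sdp$data)
  expect_identical(a$baseline$data, b$baseline$data)
  ## different subject / window / condition use distinct streams
  c2 <- simulate_source_epochs(cfg, 3, "WE-IL")
  expect_false(identical(a$sdp$data, c2$sdp$data))
  expect_false(identical(a$sdp$data, a$baseline$data))
})

test_that("epoch dimensions and metadata follow the configuration", {
  cfg <- tiny_config(seed = 2L)
  se <- simulate_source_epochs(cfg, 1, "WE-IT")
  expect_equal(dim(se$sdp$data), c(10, 8, 500))
  expect_equal(se$sdp$sampling_rate, 250)
  expect_equal(se$sdp$window_tag, "sdp")
  expect_equal(se$baseline$window_tag, "baseline")
  expect_true(all(is.finite(se$sdp$data)))
})

test_that("analytic LPS matches its definition and limits", {
  band <- c(10, 12); fs <- 250; n <- 500
  ## direct evaluation of the band-averaged coherency of a pure delay
  k <- lpsnet:::band_bins(band, fs, n)
  f <- k * fs / n
  for (dl in c(0, 0.005, 0.02, 0.04)) {
    rho <- mean(exp(-2i * pi * f * dl))
    expect_equal(analytic_lps_delay(dl, band, fs, n),
                 Im(rho)^2 / (1 - Re(rho)^2 + (Re(rho)^2 == 1)),
                 tolerance = 1e-12)
  }
  ## zero delay is purely instantaneous: degenerate rule gives 0
  expect_equal(analytic_lps_delay(0, band, fs, n), 0)
})

test_that("generator produces the analytic coherence structure", {
  ## two strongly sampled nodes in one group: |rho| should approach 1 and
  ## the phase should match the planted lag difference
  cfg <- sim_config(n_rois = 4, n_channels = 8, n_trials_per_condition = 200,
                    partition_truth = list(1:4), planted_pairs = list(),
                    conditions = "WE-IT", snr_db = 30, seed = 5,
                    rt_link = list(roi = 4L, slope = 0.4, noise_sd = 0.11,
                                   intercept = 0.8, base_mix = 0.3))
  gt <- simulation_ground_truth(cfg)
  se <- simulate_source_epochs(cfg, 1, "WE-IT", gt)
  cs <- band_cross_spectra(se$sdp, band = cfg$band)
  ## phase of the coherency at the band center reflects the lag difference
  expect_gt(Mod(cs$rho[1, 2]), 0.9)
  l <- lagged_phase_synchronization(cs)$values
  an <- analytic_lps_delay(gt$node_lags[2] - gt$node_lags[1], cfg$band, 250, 500)
  expect_lt(abs(l[1, 2] - an), 0.15)
})

test_that("ground truth plants the documented structures", {
  cfg <- tiny_config(seed = 3L)
  gt <- simulation_ground_truth(cfg)
  expect_equal(gt$partition, rep(1:4, each = 2), ignore_attr = TRUE)
  expect_true(all(gt$node_lags >= cfg$lag_range[1] & gt$node_lags <= cfg$lag_range[2]))
  ## IL boost applies only to planted pairs in the SDP window
  cb <- gt$coherence[["WE-IL"]]$baseline
  cs <- gt$coherence[["WE-IL"]]$sdp
  g <- gt$partition
  expect_gt(mean(cs[g == 1, g == 2]), mean(cb[g == 1, g == 2]))
  ## non-planted pairs cannot increase; the boosted bridges take a larger
  ## share of the planted groups' (normalized) latent power, so pairs
  ## touching a planted group are mildly diluted
  expect_lt(mean(cs[g == 1, g == 3]), mean(cb[g == 1, g == 3]) + 1e-12)
  ## IT condition has no SDP boost
  expect_equal(gt$coherence[["WE-IT"]]$sdp[g == 1, g == 2],
               gt$coherence[["WE-IT"]]$baseline[g == 1, g == 2])
  ## subject mean response times are positive
  expect_true(all(gt$rt_mean > 0))
})

test_that("leadfield geometry is resolvable and average-reference consistent", {
  lf <- make_leadfield(32, 28, seed = 4)
  expect_equal(dim(lf$gain), c(32, 28))
  ## columns centred for common-average consistency
  expect_lt(max(abs(colMeans(lf$gain))), 1e-12)
  ## sources live on the cortical shell under the electrode cap
  expect_true(all(lf$source_positions[, 3] > 0))
  expect_equal(sqrt(rowSums(lf$source_positions^2)), rep(0.9, 28),
               tolerance = 1e-9)
  ## no two sources coincide
  dmin <- min(dist(lf$source_positions))
  expect_gt(dmin, 0.01)
})

test_that("scalp projection is instantaneous and seeded", {
  cfg <- tiny_config(seed = 6L)
  se <- simulate_source_epochs(cfg, 1, "WE-IT")
  lf <- make_leadfield(cfg$n_channels, cfg$n_rois, seed = 6)
  ch1 <- project_to_channels(se$sdp, lf, sensor_snr_db = Inf)
  expect_equal(dim(ch1$data), c(10, 16, 500))
  ## noiseless projection is exactly G %*% s sample by sample
  expect_equal(ch1$data[3, , 100], drop(lf$gain %*% se$sdp$data[3, , 100]),
               tolerance = 1e-12)
  ch2 <- project_to_channels(se$sdp, lf, sensor_snr_db = 20, seed = 1)
  ch3 <- project_to_channels(se$sdp, lf, sensor_snr_db = 20, seed = 1)
  expect_identical(ch2$data, ch3$data)
})

test_that("behavior tables encode the planted engagement link", {
  cfg <- tiny_config(seed = 8L)
  gt <- simulation_ground_truth(cfg)
  beh <- simulate_behavior(gt, cfg)
  expect_equal(nrow(beh$table), 4 * 2 * 10)
  expect_true(all(beh$table$response_time > 0))
  means <- tapply(beh$table$response_time[beh$table$condition == "WE-IL"],
                  beh$table$subject[beh$table$condition == "WE-IL"], mean)
  expect_equal(as.numeric(means), as.numeric(gt$rt_mean[, "WE-IL"]),
               tolerance = 0.1)
})
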