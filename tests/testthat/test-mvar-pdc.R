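test_that("least-squares fit recovers known order-1 coefficients", {
  A1 <- matrix(c(0.5, 0.4, 0, 0.5), 2, 2)
  rec <- simulate_mvar_eeg(coupling_spec(A1), 40, 250, seed = 3)
  fit <- fit_mvar(rec$data, 1)
  expect_lt(max(abs(fit$coeffs[1, , ] - A1)), 0.05)
  expect_equal(fit$resid_cov, t(fit$resid_cov))
  expect_gt(min(eigen(fit$resid_cov, only.values = TRUE)$values), -1e-10)
})

test_that("white-noise fits shrink to zero coefficients", {
  sp <- coupling_spec(array(0, c(1, 2, 2)))
  rec <- simulate_mvar_eeg(sp, 40, 250, seed = 8)
  fit <- fit_mvar(rec$data, 2)
  expect_lt(max(abs(fit$coeffs)), 0.1)
})

test_that("linearly dependent channels are rejected with a diagnostic", {
  set.seed(2)
  x <- matrix(rnorm(600), 2)
  dup <- rbind(x, x[1, ])
  expect_error(fit_mvar(dup, 2), "linearly")
  expect_error(fit_mvar(x, 400), "too short")
})

test_that("AIC selects the generating order for a strong order-3 model", {
  co <- array(0, c(3, 2, 2))
  a <- ar2_oscillator(12, 250, 0.8)
  co[1, 1, 1] <- a[1]; co[2, 1, 1] <- a[2]
  co[1, 2, 2] <- 0.4; co[3, 2, 2] <- 0.3; co[3, 2, 1] <- 0.35
  sp3 <- coupling_spec(co)
  wn <- coupling_spec(array(0, c(1, 2, 2)))
  sel <- seln <- integer(20)
  for (r in 1:20) {
    sel[r] <- select_order_aic(
      slide_windows(simulate_mvar_eeg(sp3, 60, 250, seed = r)), 1, 8)
    seln[r] <- select_order_aic(
      slide_windows(simulate_mvar_eeg(wn, 20, 250, seed = 100 + r)), 1, 8)
  }
  expect_gte(sum(sel %in% 2:4), 18)
  expect_gte(sum(seln <= 2), 18)
  expect_true(all(sel >= 1 & sel <= 8))
})

test_that("transfer matrix matches hand-evaluated cases", {
  m0 <- transfer_matrix(array(0, c(1, 3, 3)), c(5, 10), 250)
  for (f in 1:2) expect_equal(m0[f, , ], diag(3) + 0i)
  ms <- transfer_matrix(matrix(0.5, 1, 1), 0, 250)
  expect_equal(ms[1, 1, 1], 0.5 + 0i)
  A1 <- matrix(c(0.5, 0.4, 0, 0.5), 2, 2)
  m2 <- transfer_matrix(A1, 0, 250)
  expect_equal(Re(m2[1, , ]), matrix(c(0.5, -0.4, 0, 0.5), 2, 2))
})

test_that("PDC matches the direct-evaluation oracle across models and freqs", {
  set.seed(5)
  for (rep in 1:20) {
    m <- sample(2:4, 1); p <- sample(1:3, 1)
    co <- array(rnorm(p * m * m, sd = 0.15), c(p, m, m))
    freqs <- c(0.5, 5, 12, 25, 60)
    sp <- pdc(transfer_matrix(co, freqs, 250))
    for (fi in seq_along(freqs))
      expect_equal(sp$values[fi, , ], pdc_direct(co, freqs[fi], 250),
                   tolerance = 1e-12)
  }
})

test_that("uncoupled models give identity-structured PDC", {
  co <- array(0, c(1, 3, 3))
  diag(co[1, , ]) <- c(0.3, 0.5, 0.7)
  co2 <- co
  sp <- pdc(transfer_matrix(co2, c(1, 10, 30), 250))
  for (fi in 1:3) {
    v <- sp$values[fi, , ]
    expect_equal(diag(v), rep(1, 3))
    expect_equal(v[row(v) != col(v)], rep(0, 6))
  }
})

test_that("band averaging is the arithmetic mean with a zeroed diagonal", {
  # hand-built spectrum: constant c off-diagonal at every frequency
  freqs <- default_freq_grid()
  nf <- length(freqs)
  vals <- array(0.3, c(nf, 3, 3))
  fake <- structure(list(freqs = freqs, values = vals, transfer = NULL),
                    class = "pdc_spectrum")
  bc <- band_average(fake)
  for (b in names(bc)) {
    expect_equal(bc[[b]]$matrix[row(diag(3)) != col(diag(3))], rep(0.3, 6))
    expect_equal(diag(bc[[b]]$matrix), rep(0, 3))
  }
  # two in-band values average: entries 0.2 and 0.4 at the two delta freqs
  freqs2 <- c(2, 3)
  vals2 <- array(0, c(2, 2, 2))
  vals2[1, 2, 1] <- 0.2; vals2[2, 2, 1] <- 0.4
  fake2 <- structure(list(freqs = freqs2, values = vals2, transfer = NULL),
                     class = "pdc_spectrum")
  bc2 <- band_average(fake2, edges = list(delta = c(1, 4)))
  expect_equal(bc2$delta$matrix[2, 1], 0.3)
  expect_error(band_average(fake2, edges = list(beta = c(13, 30))),
               "beta")
})

test_that("squared-PDC averaging squares before the mean", {
  freqs2 <- c(2, 3)
  vals2 <- array(0, c(2, 2, 2))
  vals2[1, 2, 1] <- 0.2; vals2[2, 2, 1] <- 0.4
  fake2 <- structure(list(freqs = freqs2, values = vals2, transfer = NULL),
                     class = "pdc_spectrum")
  bc <- band_average(fake2, edges = list(delta = c(1, 4)), squared = TRUE)
  expect_equal(bc$delta$matrix[2, 1], (0.04 + 0.16) / 2)
})

test_that("fitted PDC satisfies the column normalization identity", {
  pair <- make_task_pair(n_channels = 4, effect_size = 1, seed = 13,
                         fs = 250, duration_s = 12)
  ws <- slide_windows(pair$play)
  for (w in ws$windows) {
    sp <- window_pdc(w, 6, default_freq_grid(), 250)
    ss <- apply(sp$values^2, c(1, 3), sum)
    expect_lt(max(abs(ss - 1)), 1e-10)
    expect_true(all(sp$values >= 0 & sp$values <= 1 + 1e-12))
  }
})

test_that("bootstrap masks find a planted direction and keep a false diagonal",
{
  rec <- simulate_mvar_eeg(osc_pair_spec(0.4), 12, 250, seed = 19)
  masks <- bootstrap_significance(slide_windows(rec), 3,
                                  default_freq_grid(), 250,
                                  n_boot = 100, alpha = 0.05, seed = 20)
  expect_true(masks$alpha[2, 1])      # 1 -> 2 planted, source resonates ~10 Hz
  expect_false(masks$alpha[1, 2])
  for (b in names(masks)) expect_false(any(diag(masks[[b]])))
  expect_error(bootstrap_significance(slide_windows(rec), 3,
                                      default_freq_grid(), 250,
                                      n_boot = 10, seed = 1))
})
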