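#' Coupling specification for the synthetic MVAR generator
#'
#' Defines the generative multivariate autoregression
#' \deqn{X(t) = \sum_{r=1}^{p} A(r) X(t-r) + E(t)}
#' from which synthetic EEG is drawn: `coeffs[r, i, j]` is the lag-`r`
#' influence of source channel `j` on target channel `i`, and `E(t)` is
#' zero-mean Gaussian noise with diagonal covariance `diag(noise_scale^2)`.
#' The spec is rejected unless the companion matrix of the coefficient
#' tensor has spectral radius below 1 (stationarity).
#'
#' @param coeffs numeric array of dimension `(order, n_channels, n_channels)`
#'   indexed (lag, target, source). A plain `n x n` matrix is accepted for
#'   order 1.
#' @param noise_scale positive per-channel innovation standard deviations;
#'   recycled to the number of channels.
#' @param description free-text note carried into recording sidecars.
#'
#' @return An object of class `coupling_spec` with fields `n_channels`,
#'   `order`, `coeffs`, `noise_scale`, `description` and the computed
#'   `spectral_radius`.
#' @export
coupling_spec <- function(coeffs, noise_scale = 1, description = "") {
  if (is.matrix(coeffs)) coeffs <- array(coeffs, c(1L, dim(coeffs)))
  d <- dim(coeffs)
  if (length(d) != 3L || d[2] != d[3])
    stop("coeffs must be an array (lag, target, source) with square slices")
  if (!all(is.finite(coeffs))) stop("coeffs must be finite")
  m <- d[2]; p <- d[1]
  noise_scale <- rep_len(as.numeric(noise_scale), m)
  if (any(noise_scale <= 0)) stop("noise_scale must be positive")
  rho <- companion_spectral_radius(coeffs)
  if (rho >= 1)
    stop(sprintf(paste0("coupling spec is non-stationary: companion spectral",
                        " radius %.4f >= 1"), rho))
  structure(list(n_channels = m, order = p, coeffs = coeffs,
                 noise_scale = noise_scale, description = description,
                 spectral_radius = rho),
            class = "coupling_spec")
}

#' Spectral radius of the VAR companion matrix
#'
#' @param coeffs array (lag, target, source).
#' @return Largest eigenvalue modulus of the stacked companion form.
#' @export
companion_spectral_radius <- function(coeffs) {
  d <- dim(coeffs); p <- d[1]; m <- d[2]
  comp <- matrix(0, m * p, m * p)
  for (r in seq_len(p))
    comp[seq_len(m), (r - 1L) * m + seq_len(m)] <- coeffs[r, , ]
  if (p > 1L)
    comp[m + seq_len(m * (p - 1L)), seq_len(m * (p - 1L))] <-
      diag(m * (p - 1L))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' AR(2) coefficients of a damped oscillator
#'
#' Places a complex pole pair at radius `rho` and frequency `f0`, giving a
#' stochastic oscillation with a spectral peak near `f0`.
#'
#' @param f0 resonance frequency in Hz.
#' @param fs sampling rate in Hz.
#' @param rho pole radius in (0, 1); closer to 1 means a sharper peak.
#' @return Numeric `c(a1, a2)` with `a1 = 2 rho cos(2 pi f0 / fs)`,
#'   `a2 = -rho^2`.
#' @export
ar2_oscillator <- function(f0, fs, rho) {
  stopifnot(rho > 0, rho < 1, f0 > 0, f0 < fs / 2)
  c(2 * rho * cos(2 * pi * f0 / fs), -rho^2)
}

#' Simulate multichannel EEG from an MVAR coupling spec
#'
#' Draws Gaussian innovations, runs the autoregression from a zero state and
#' discards a burn-in of `max(1000, 10 * order)` samples so the returned
#' series is a draw from the stationary distribution. Identical seeds give
#' bit-identical output.
#'
#' @param spec a [coupling_spec()].
#' @param duration_s session length in seconds (after burn-in).
#' @param fs sampling rate in Hz.
#' @param seed integer RNG seed.
#' @param subject_id,condition,channel_labels recording metadata; labels
#'   default to `Ch1..Chm` (or the 16-channel 10-20 montage when `m == 16`).
#' @return An [eeg_recording()] of exactly `round(duration_s * fs)` samples,
#'   with the generating spec's description and seed attached as attributes.
#' @export
simulate_mvar_eeg <- function(spec, duration_s, fs, seed,
                              subject_id = "S01", condition = "rest",
                              channel_labels = NULL) {
  stopifnot(inherits(spec, "coupling_spec"), duration_s > 0, fs > 0)
  m <- spec$n_channels; p <- spec$order
  n_keep <- as.integer(round(duration_s * fs))
  if (n_keep < 10L * p)
    stop("duration_s * fs must be at least 10 * order samples")
  burn <- max(1000L, 10L * p)
  n_tot <- n_keep + burn
  # flattened coefficient matrix: m x (m*p), lag blocks side by side
  cmat <- matrix(0, m, m * p)
  for (r in seq_len(p)) cmat[, (r - 1L) * m + seq_len(m)] <- spec$coeffs[r, , ]
  set.seed(as.integer(seed))
  innov <- matrix(stats::rnorm(m * n_tot), m, n_tot) * spec$noise_scale
  x <- matrix(0, m, n_tot + p)            # p zero columns of pre-history
  for (t in seq_len(n_tot)) {
    lags <- x[, t + p - seq_len(p), drop = FALSE]   # lag 1..p
    x[, t + p] <- cmat %*% as.vector(lags) + innov[, t]
  }
  out <- x[, p + burn + seq_len(n_keep), drop = FALSE]
  if (is.null(channel_labels))
    channel_labels <- if (m == 16L) montage_1020_16() else paste0("Ch", 1:m)
  rec <- eeg_recording(out, fs = fs, channel_labels = channel_labels,
                       subject_id = subject_id, condition = condition)
  attr(rec, "seed") <- as.integer(seed)
  attr(rec, "spec_description") <- spec$description
  attr(rec, "ground_truth") <- attr(spec, "ground_truth")
  rec
}

#' Damped-cosine coupling kernel concentrated at one frequency
#'
#' Multi-lag cross-channel coefficients `k_r = gamma^(r-1) cos(2 pi f0 r /
#' fs)`, normalized to unit L1 norm. Unlike a single lag-1 coefficient
#' (whose spectral transfer is flat in frequency), this kernel concentrates
#' the coupling's spectral numerator near `f0`, so planted interactions stay
#' band-specific in the PDC sense.
#'
#' @param f0 center frequency in Hz.
#' @param fs sampling rate in Hz.
#' @param n_lags kernel length (default 8).
#' @param gamma per-lag damping in (0, 1) (default 0.85).
#' @return Numeric vector of `n_lags` lag coefficients with unit L1 norm.
#' @export
coupling_kernel <- function(f0, fs, n_lags = 8, gamma = 0.85) {
  r <- seq_len(n_lags)
  k <- gamma^(r - 1) * cos(2 * pi * f0 * r / fs)
  k / sum(abs(k))
}

# Build the task-pair coupling spec for one condition. Channels are damped
# AR(2) oscillators; the first half resonate in the beta band (20 Hz, pole
# radius 0.74), the second half in the theta band (6 Hz, radius 0.58).
# Cross-channel coupling uses the band-tuned damped-cosine kernel
# (coupling_kernel) so planted interactions concentrate in the group's own
# rhythm band. The two conditions differ in topology as well as band:
#   play: dense directed clique among the beta oscillators (per-edge L1
#         budget 0.15 * effect_size / (group size - 1)),
#   rest: directed ring among the theta oscillators (per-edge budget
#         0.15 * effect_size).
# The clique gives the play condition's beta-band graph high local
# clustering; the ring carries equally strong theta-band flow but no local
# clustering, so any spectral leakage into the beta band cannot mimic the
# clique. The companion radius stays below 1 for effect sizes up to ~1.2;
# stronger coupling is rejected by the stationarity gate.
task_spec <- function(n_channels, effect_size, condition, model_fs) {
  m <- n_channels
  beta_set <- seq_len(ceiling(m / 2))
  theta_set <- setdiff(seq_len(m), beta_set)
  n_lags <- 8L
  p <- max(2L, n_lags)
  coeffs <- array(0, c(p, m, m))
  ab <- ar2_oscillator(20, model_fs, rho = 0.74)
  at <- ar2_oscillator(6, model_fs, rho = 0.58)
  for (i in seq_len(m)) {
    a <- if (i %in% beta_set) ab else at
    coeffs[1, i, i] <- a[1]; coeffs[2, i, i] <- a[2]
  }
  truth <- matrix(FALSE, m, m)
  if (effect_size > 0) {
    if (condition == "play") {
      k <- coupling_kernel(20, model_fs, n_lags) * 0.15 * effect_size /
        (length(beta_set) - 1)
      for (i in beta_set) for (j in beta_set) if (i != j) {
        coeffs[seq_len(n_lags), i, j] <- k
        truth[i, j] <- TRUE
      }
    } else {
      k <- coupling_kernel(6, model_fs, n_lags) * 0.15 * effect_size
      g <- length(theta_set)
      for (jj in seq_len(g)) {
        j <- theta_set[jj]                    # source
        i <- theta_set[jj %% g + 1L]          # target: next around the ring
        coeffs[seq_len(n_lags), i, j] <- k
        truth[i, j] <- TRUE
      }
    }
  }
  spec <- coupling_spec(
    coeffs, noise_scale = 1,
    description = sprintf("task_spec(%s, m=%d, effect=%g)", condition, m,
                          effect_size))
  attr(spec, "ground_truth") <- list(
    adjacency = truth,
    band = if (condition == "play") "beta" else "theta")
  spec
}

#' Simulate a play/rest recording pair with a planted band-specific contrast
#'
#' The "play" condition carries a dense directed coupling clique among the
#' beta-band (20 Hz) oscillators, giving its beta-band network high local
#' clustering; "rest" carries equally strong directed coupling among the
#' theta-band (6 Hz) oscillators, but arranged as a ring, which transports
#' theta-band flow without local clustering. Coupling uses band-tuned
#' damped-cosine lag kernels ([coupling_kernel()]) so each condition's
#' planted structure concentrates in its own rhythm band. With
#' `effect_size = 0` the two conditions are identically distributed (no
#' cross-channel coupling in either). The planted directed adjacency is
#' attached to each recording as the `ground_truth` attribute.
#'
#' The autoregression is defined at the analysis rate `model_fs` (250 Hz);
#' when `fs > model_fs` the band-limited series is polyphase-interpolated up
#' to the requested digitization rate, emulating a 1000-Hz acquisition of a
#' sub-30-Hz process.
#'
#' @param n_channels number of channels (>= 3; default 16).
#' @param effect_size nonnegative coupling strength multiplier; the default
#'   1 plants per-edge kernel L1 budgets of `0.15 / (group size - 1)`
#'   (clique) and `0.15` (ring). Values above ~1.2 violate stationarity and
#'   are rejected.
#' @param seed integer seed; the two conditions use `seed` and `seed + 1`.
#' @param fs output sampling rate (must be an integer multiple of
#'   `model_fs`); default 1000 Hz.
#' @param duration_s session length in seconds; default 180 (a 3-minute
#'   session).
#' @param model_fs rate at which the MVAR structure is defined; default 250.
#' @param subject_id subject identifier stamped on both recordings.
#' @return List with elements `play` and `rest`, both [eeg_recording()]s.
#' @export
make_task_pair <- function(n_channels = 16, effect_size = 1, seed = 1,
                           fs = 1000, duration_s = 180, model_fs = 250,
                           subject_id = "S01") {
  if (n_channels < 3)
    stop("n_channels must be >= 3: an asymmetric directed network needs at ",
         "least two oscillator groups with a couplable pair")
  if (effect_size < 0) stop("effect_size must be >= 0")
  q <- fs / model_fs
  if (abs(q - round(q)) > 1e-9 || q < 1)
    stop("fs must be a positive integer multiple of model_fs")
  q <- as.integer(round(q))
  one <- function(condition, sd) {
    spec <- task_spec(n_channels, effect_size, condition, model_fs)
    rec <- simulate_mvar_eeg(spec, duration_s, model_fs, seed = sd,
                             subject_id = subject_id, condition = condition)
    if (q > 1L) {
      up <- t(apply(rec$data, 1, function(ch) signal::interp(ch, q)))
      rec2 <- eeg_recording(up, fs = fs, channel_labels = rec$channel_labels,
                            subject_id = subject_id, condition = condition)
      attr(rec2, "seed") <- attr(rec, "seed")
      attr(rec2, "spec_description") <- attr(rec, "spec_description")
      attr(rec2, "ground_truth") <- attr(rec, "ground_truth")
      rec <- rec2
    }
    rec
  }
  list(play = one("play", as.integer(seed)),
       rest = one("rest", as.integer(seed) + 1L))
}

#' Amplitude-modulated test tone with known envelope
#'
#' Returns `x(t) = (1 + depth * cos(2 pi f_env t)) * cos(2 pi f_c t)`
#' together with its exact envelope, as a ground-truth fixture for envelope
#' demodulation.
#'
#' @param env_freq modulation frequency in Hz (must be well below
#'   `carrier_freq`).
#' @param carrier_freq carrier frequency in Hz (below Nyquist).
#' @param depth modulation depth in `[0, 1)`.
#' @param duration_s,fs signal length and sampling rate.
#' @return List with `x`, `envelope`, `t` (seconds) and `fs`.
#' @export
make_am_fm_signal <- function(env_freq, carrier_freq, depth, duration_s, fs) {
  if (carrier_freq >= fs / 2)
    stop("carrier_freq must be below the Nyquist rate fs/2")
  if (env_freq >= carrier_freq / 2)
    stop("env_freq must be well below carrier_freq")
  if (depth < 0 || depth >= 1) stop("depth must be in [0, 1)")
  t <- seq(0, duration_s, by = 1 / fs)
  t <- t[-length(t)]
  env <- 1 + depth * cos(2 * pi * env_freq * t)
  list(x = env * cos(2 * pi * carrier_freq * t), envelope = env, t = t,
       fs = fs)
}
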