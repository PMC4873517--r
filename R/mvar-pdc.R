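#' Fit a multivariate autoregressive (MVAR) model by least squares
#'
#' Estimates the model
#' \deqn{X(t) = \sum_{r=1}^{p} A(r) X(t-r) + E(t)}
#' by ordinary least squares on lagged regressors: the coefficients minimize
#' the summed squared one-step-ahead residuals. The residual covariance is
#' the sample covariance of the residuals (normalized by the effective
#' sample count), and the model's AIC is
#' `n_eff * ln det(Sigma) + 2 * p * m^2`.
#'
#' @param window numeric matrix, channels (m) x samples (n), with
#'   `n > m * order_p + 1`.
#' @param order_p model order (>= 1).
#' @return An object of class `mvar_model`: `order_p`, `coeffs` (array lag x
#'   target x source), `resid_cov`, `residuals` (m x n_eff), `n_samples_used`
#'   and `aic`.
#' @export
fit_mvar <- function(window, order_p) {
  window <- as.matrix(window)
  m <- nrow(window); n <- ncol(window); p <- as.integer(order_p)
  stopifnot(p >= 1)
  if (n <= m * p + 1)
    stop(sprintf("window too short: need more than m*p + 1 = %d samples, got %d",
                 m * p + 1, n))
  n_eff <- n - p
  y <- window[, (p + 1):n, drop = FALSE]                 # m x n_eff
  z <- matrix(0, m * p, n_eff)                           # stacked lags
  for (r in seq_len(p))
    z[(r - 1L) * m + seq_len(m), ] <- window[, (p + 1 - r):(n - r),
                                             drop = FALSE]
  zzt <- tcrossprod(z)
  qz <- qr(zzt)
  if (qz$rank < nrow(zzt)) {
    dup <- which(duplicated(round(window, 12), MARGIN = 1))
    extra <- if (length(dup))
      paste0(" (duplicated channel rows: ", paste(dup, collapse = ", "), ")")
    else ""
    stop("rank-deficient lagged regressor matrix; channels are linearly ",
         "dependent", extra)
  }
  b <- t(solve(qz, tcrossprod(z, y)))                    # m x (m*p)
  resid <- y - b %*% z
  sigma <- tcrossprod(resid) / n_eff
  sigma <- (sigma + t(sigma)) / 2
  ld <- determinant(sigma, logarithm = TRUE)
  logdet <- if (ld$sign > 0) as.numeric(ld$modulus) else -Inf
  coeffs <- array(0, c(p, m, m))
  for (r in seq_len(p)) coeffs[r, , ] <- b[, (r - 1L) * m + seq_len(m)]
  structure(list(order_p = p, coeffs = coeffs, resid_cov = sigma,
                 residuals = resid, n_samples_used = n_eff,
                 aic = n_eff * logdet + 2 * p * m^2),
            class = "mvar_model")
}

#' Select the MVAR order by AIC across windows
#'
#' Fits every window at each candidate order and returns the order
#' minimizing the mean AIC, giving one subject-level order for the whole
#' recording.
#'
#' @param windows a `window_set` (or plain list of channel x sample
#'   matrices).
#' @param p_min,p_max candidate order range (`p_max >= p_min >= 1`).
#' @return The selected integer order.
#' @export
select_order_aic <- function(windows, p_min = 2, p_max = 20) {
  stopifnot(p_max >= p_min, p_min >= 1)
  wl <- if (inherits(windows, "window_set")) windows$windows else windows
  orders <- p_min:p_max
  mean_aic <- vapply(orders, function(p)
    mean(vapply(wl, function(w) fit_mvar(w, p)$aic, numeric(1))),
    numeric(1))
  orders[which.min(mean_aic)]
}

#' Spectral transfer matrix of an MVAR model
#'
#' \deqn{\bar A_{ij}(f) = \delta_{ij} - \sum_{r=1}^{p} a_{ij}(r)
#'   e^{-i 2\pi (f/f_s) r}}
#' with the frequency normalized to cycles per sample.
#'
#' @param model an `mvar_model` (or a coefficient array lag x target x
#'   source).
#' @param freqs frequencies in Hz, inside `(0, fs/2]` (f = 0 is accepted for
#'   analytic checks).
#' @param fs sampling rate in Hz.
#' @return Complex array `(freq, target, source)`.
#' @export
transfer_matrix <- function(model, freqs, fs) {
  coeffs <- if (inherits(model, "mvar_model")) model$coeffs else model
  if (is.matrix(coeffs)) coeffs <- array(coeffs, c(1L, dim(coeffs)))
  p <- dim(coeffs)[1]; m <- dim(coeffs)[2]
  nf <- length(freqs)
  if (any(freqs < 0) || any(freqs > fs / 2))
    stop("freqs must lie in [0, fs/2]")
  a_f <- array(0i, c(nf, m, m))
  for (r in seq_len(p)) {
    phase <- exp(-1i * 2 * pi * (freqs / fs) * r)
    a_f <- a_f + outer(phase, matrix(coeffs[r, , ], m, m))
  }
  abar <- -a_f
  for (i in seq_len(m)) abar[, i, i] <- 1 + abar[, i, i]
  dimnames(abar) <- list(NULL, NULL, NULL)
  attr(abar, "freqs") <- freqs
  abar
}

#' Partial directed coherence from a transfer matrix
#'
#' \deqn{PDC_{ij}(f) = \frac{|\bar A_{ij}(f)|}
#'   {\sqrt{\bar a_j^H(f) \bar a_j(f)}}}
#' i.e. each entry of the transfer matrix normalized by the Euclidean norm
#' of its own source column, so the squared outflows of every source sum to
#' 1 at every frequency. `PDC_ij` measures the direction and intensity of
#' information flow from channel `j` to channel `i`.
#'
#' @param transfer complex array `(freq, target, source)` from
#'   [transfer_matrix()].
#' @return Object of class `pdc_spectrum`: `freqs`, `values` (array freq x
#'   target x source, entries in `[0, 1]`) and `transfer`.
#' @export
pdc <- function(transfer) {
  if (!all(is.finite(Re(transfer))) || !all(is.finite(Im(transfer))))
    stop("transfer matrix must be finite")
  d <- dim(transfer)
  absa <- Mod(transfer)
  colnorm <- sqrt(colSums(aperm(absa^2, c(2, 1, 3))))   # freq x source
  if (any(colnorm == 0))
    stop("zero source-column norm in the transfer matrix; the MVAR fit is ",
         "numerically degenerate")
  values <- absa / aperm(array(colnorm, c(d[1], d[3], d[2])), c(1, 3, 2))
  structure(list(freqs = attr(transfer, "freqs"), values = values,
                 transfer = transfer),
            class = "pdc_spectrum")
}

#' Fit one window and return its PDC spectrum
#'
#' @param window channels x samples matrix.
#' @param order_p MVAR order.
#' @param freqs frequency grid in Hz.
#' @param fs sampling rate in Hz.
#' @return A `pdc_spectrum`.
#' @export
window_pdc <- function(window, order_p, freqs, fs)
  pdc(transfer_matrix(fit_mvar(window, order_p), freqs, fs))

#' Average PDC spectra into rhythm-band connectivity matrices
#'
#' For each band, PDC values are averaged over the in-band grid frequencies
#' within each window and then arithmetically across windows; the diagonal
#' is forced to zero (self-flows are not part of the network).
#'
#' @param pdc_list a `pdc_spectrum` or list of them (one per window), all on
#'   the same frequency grid.
#' @param edges band definition, as from [band_edges()].
#' @param squared average squared PDC instead of the magnitude (default
#'   FALSE).
#' @param channel_labels optional node labels attached to each matrix.
#' @return Named list of `band_connectivity` objects: `band`, `matrix`
#'   (target x source, zero diagonal), `n_windows`, `sig_mask` (NULL until
#'   [bootstrap_significance()] is applied).
#' @export
band_average <- function(pdc_list, edges = band_edges(), squared = FALSE,
                         channel_labels = NULL) {
  if (inherits(pdc_list, "pdc_spectrum")) pdc_list <- list(pdc_list)
  freqs <- pdc_list[[1]]$freqs
  membership <- band_membership(freqs, edges)
  out <- list()
  for (b in names(edges)) {
    idx <- which(membership == b)
    if (length(idx) == 0)
      stop("frequency grid has no points in band '", b, "'")
    mats <- lapply(pdc_list, function(sp) {
      v <- sp$values[idx, , , drop = FALSE]
      if (squared) v <- v^2
      colMeans(v)                     # mean over in-band frequencies
    })
    avg <- Reduce(`+`, mats) / length(mats)
    diag(avg) <- 0
    if (!is.null(channel_labels))
      dimnames(avg) <- list(channel_labels, channel_labels)
    out[[b]] <- structure(list(band = b, matrix = avg,
                               n_windows = length(mats), sig_mask = NULL),
                          class = "band_connectivity")
  }
  out
}

#' Bootstrap edge significance for band-averaged PDC
#'
#' Builds a causal null by surrogate refitting: each bootstrap replicate
#' regenerates the whole session from its fitted MVAR model with all
#' cross-channel coefficients zeroed (each channel driven only by its own
#' past) and residuals independently resampled per channel, which destroys
#' directed cross-links while preserving each channel's spectrum. The
#' surrogate session is cut into the same sliding windows as the observed
#' data — so the null statistic inherits the between-window correlation
#' induced by overlap — and the full model is refitted per window with
#' band-averaged PDC recomputed. An edge is significant when the observed
#' band value exceeds the `(1 - alpha)` quantile of its null distribution.
#'
#' @param windows a `window_set` (or list of matrices).
#' @param order_p MVAR order used throughout.
#' @param freqs frequency grid in Hz.
#' @param fs sampling rate in Hz.
#' @param edges band definition.
#' @param n_boot number of bootstrap replicates (>= 100).
#' @param alpha significance level in (0, 1).
#' @param seed integer seed.
#' @param squared propagate the squared-PDC flag of the observed statistic.
#' @return Named list (per band) of logical significance masks (target x
#'   source, diagonal FALSE), with the observed matrices and null quantiles
#'   attached as attributes `observed` and `threshold`.
#' @export
bootstrap_significance <- function(windows, order_p, freqs, fs,
                                   edges = band_edges(), n_boot = 200,
                                   alpha = 0.05, seed = 1, squared = FALSE) {
  stopifnot(n_boot >= 100, alpha > 0, alpha < 1)
  if (inherits(windows, "window_set")) {
    wl <- windows$windows
    hop <- windows$hop
  } else {
    wl <- windows
    hop <- ncol(wl[[1]])                  # plain list: treat as abutting
  }
  fits <- lapply(wl, fit_mvar, order_p = order_p)
  observed <- band_average(lapply(fits, function(f)
    pdc(transfer_matrix(f, freqs, fs))), edges, squared = squared)
  m <- nrow(observed[[1]]$matrix)
  p <- order_p
  wlen <- ncol(wl[[1]])
  # reconstruct the session the windows were cut from (windows are views
  # spaced hop samples apart), then fit the session-level surrogate model
  n_win <- length(wl)
  session <- matrix(0, m, (n_win - 1L) * hop + wlen)
  for (k in seq_len(n_win))
    session[, (k - 1L) * hop + seq_len(wlen)] <- wl[[k]]
  sfit <- fit_mvar(session, p)
  self_ar <- vapply(seq_len(m), function(ch) sfit$coeffs[, ch, ch],
                    numeric(p))
  res <- sfit$residuals
  n_res <- ncol(res)
  n_sess <- ncol(session)
  set.seed(as.integer(seed))
  null_vals <- lapply(names(edges), function(b)
    array(NA_real_, c(n_boot, m, m)))
  names(null_vals) <- names(edges)
  for (bt in seq_len(n_boot)) {
    # surrogate session: per channel a univariate AR(p) driven by its own
    # resampled session residuals, seeded with the observed pre-history
    surro <- t(vapply(seq_len(m), function(ch) {
      e <- res[ch, sample.int(n_res, n_sess, replace = TRUE)]
      as.numeric(stats::filter(e, self_ar[, ch], method = "recursive",
                               init = rev(session[ch, seq_len(p)])))
    }, numeric(n_sess)))
    surro_pdc <- lapply(seq_len(n_win), function(k)
      pdc(transfer_matrix(
        fit_mvar(surro[, (k - 1L) * hop + seq_len(wlen), drop = FALSE], p),
        freqs, fs)))
    bands_bt <- band_average(surro_pdc, edges, squared = squared)
    for (b in names(edges)) null_vals[[b]][bt, , ] <- bands_bt[[b]]$matrix
  }
  out <- list()
  for (b in names(edges)) {
    thr <- apply(null_vals[[b]], c(2, 3), stats::quantile,
                 probs = 1 - alpha, names = FALSE)
    mask <- observed[[b]]$matrix > thr
    diag(mask) <- FALSE
    attr(mask, "observed") <- observed[[b]]$matrix
    attr(mask, "threshold") <- thr
    out[[b]] <- mask
  }
  out
}
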