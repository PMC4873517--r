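#' Local mean decomposition (LMD)
#'
#' Iteratively splits a signal into product functions (PFs), each the
#' elementwise product of a nonnegative envelope and a frequency-modulated
#' carrier bounded by 1, plus a monotone residual. Within each PF, sifting
#' alternates two steps until the local magnitude is flat: (1) local means
#' and local magnitudes are formed from midpoints of successive extrema and
#' smoothed with a moving average whose span is the largest inter-extrema
#' gap (forced odd, boundary handled by mirror extension); (2) the mean is
#' subtracted and the result divided by the magnitude. The product of the
#' magnitude functions across sifting iterations is the PF envelope.
#'
#' The decomposition is strictly additive: `sum of PFs + residual == x` to
#' numerical precision, because each PF is subtracted exactly as returned.
#'
#' @param x finite numeric signal of length >= 32.
#' @param max_pfs maximum number of product functions (default 8).
#' @param env_tol sifting stops when the smoothed local magnitude is within
#'   `env_tol` of 1 everywhere (default 0.01).
#' @param max_sift_iter cap on sifting iterations per PF (default 50).
#' @return List with `pfs` (list of `product_function`: `envelope`, `fm`,
#'   `pf`, `index`) and `residual`. A constant (or monotone) input yields an
#'   empty PF list with `residual = x`.
#' @export
lmd_decompose <- function(x, max_pfs = 8, env_tol = 0.01,
                          max_sift_iter = 50) {
  if (length(x) < 32) stop("signal must have at least 32 samples")
  if (!all(is.finite(x))) stop("signal must be finite")
  residual <- as.numeric(x)
  pfs <- list()
  while (length(pfs) < max_pfs) {
    sift <- lmd_sift(residual, env_tol, max_sift_iter)
    if (is.null(sift)) break                    # residual (near-)monotone
    pf <- sift$envelope * sift$fm
    pfs[[length(pfs) + 1L]] <- structure(
      list(envelope = sift$envelope, fm = sift$fm, pf = pf,
           index = length(pfs) + 1L),
      class = "product_function")
    residual <- residual - pf
  }
  list(pfs = pfs, residual = residual)
}

# One product function: returns list(envelope, fm) or NULL when the signal
# has too few extrema to sift (monotone/constant residual). Sifting keeps
# the iterate whose smoothed local magnitude is flattest and stops early if
# an iteration starts diverging (|s| growing well past 1), which guards the
# division by small local magnitudes near segment boundaries.
lmd_sift <- function(s, env_tol, max_sift_iter) {
  n <- length(s)
  env <- rep(1, n)
  best <- NULL
  best_score <- Inf
  stall <- 0L
  for (iter in seq_len(max_sift_iter)) {
    ext <- local_extrema(s)
    if (length(ext) < 2L) {
      if (is.null(best)) return(NULL)
      break
    }
    ma <- local_mean_magnitude(s, ext)
    score <- max(abs(ma$a - 1))
    if (score < best_score) {
      best_score <- score
      best <- list(s = s, env = env)
      stall <- 0L
    } else {
      stall <- stall + 1L
      # no progress toward a flat magnitude for several sifts: the signal
      # (e.g. broadband noise) has no cleaner AM-FM split; keep the best
      if (stall >= 3L) break
    }
    if (score <= env_tol) break
    a <- pmax(ma$a, .Machine$double.eps)
    s_new <- (s - ma$m) / a
    if (max(abs(s_new)) > 10) break          # diverging; keep best iterate
    s <- s_new
    env <- env * a
  }
  if (is.null(best)) return(NULL)
  # fold any residual FM overshoot into the envelope; the product
  # envelope*fm is unchanged and the FM part stays bounded by 1 + env_tol
  over <- max(1, max(abs(best$s)) / (1 + env_tol))
  list(envelope = best$env * over, fm = best$s / over)
}

# Indices of interior local extrema (strict sign change of the slope);
# plateaus inherit the preceding slope sign so a flat top counts once.
local_extrema <- function(x) {
  d <- sign(diff(x))
  nz <- which(d != 0)
  if (length(nz) == 0L) return(integer(0))
  idx <- cummax(seq_along(d) * (d != 0))
  idx[idx == 0L] <- nz[1]          # leading plateau inherits first real slope
  d <- d[idx]
  which(diff(d) != 0) + 1L
}

# Piecewise-constant local mean m and local magnitude a from midpoints of
# successive extrema, smoothed with an odd-span moving average. The boundary
# segments (before the first and after the last extremum) take the value of
# the adjacent segment, i.e. mirror extension of the extrema sequence.
local_mean_magnitude <- function(s, ext) {
  n <- length(s)
  v <- s[ext]
  k <- length(ext)
  seg_m <- (v[-k] + v[-1]) / 2
  seg_a <- abs(v[-k] - v[-1]) / 2
  # sample -> segment lookup: samples in [ext[j], ext[j+1]) get segment j
  seg_of <- cut(seq_len(n), breaks = c(0, ext[-1L], n + 1L),
                labels = FALSE)
  seg_of <- pmin(seg_of, k - 1L)
  span <- max(diff(ext))
  if (span %% 2L == 0L) span <- span + 1L
  list(m = moving_average(seg_m[seg_of], span),
       a = moving_average(seg_a[seg_of], span))
}

# Centered moving average with mirrored edges (odd span).
moving_average <- function(x, span) {
  if (span <= 1L) return(x)
  h <- (span - 1L) %/% 2L
  n <- length(x)
  pad <- c(x[pmin(h:1, n)], x, x[pmax(n - (1:h) + 1L, 1L)])
  cs <- cumsum(c(0, pad))
  (cs[(span + 1):(span + n)] - cs[1:n]) / span
}

#' Per-PF energy features
#'
#' Feature `j` is the mean squared amplitude of the `j`-th product function
#' (sum of squared samples divided by signal length); when fewer than `k`
#' PFs were extracted the vector is zero-padded.
#'
#' @param pfs list of product functions from [lmd_decompose()].
#' @param k feature vector length (default 4).
#' @return Numeric vector of length `k`.
#' @export
energy_features <- function(pfs, k = 4) {
  stopifnot(k >= 1)
  out <- numeric(k)
  for (j in seq_len(min(k, length(pfs)))) {
    pf <- pfs[[j]]$pf
    out[j] <- sum(pf^2) / length(pf)
  }
  out
}
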