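# Independent oracles used to cross-check the package implementation.
# These deliberately share no code with the functions they validate.

# Welch spectral peak: averaged windowed periodograms with light smoothing.
welch_peak <- function(x, fs, nseg = 2000, smooth = 9) {
  hop <- nseg %/% 2
  starts <- seq(1, length(x) - nseg + 1, by = hop)
  win <- signal::hanning(nseg)
  pg <- sapply(starts, function(s)
    Mod(stats::fft(x[s:(s + nseg - 1)] * win))[1:(nseg / 2)]^2)
  pw <- stats::filter(rowMeans(pg), rep(1 / smooth, smooth), sides = 2)
  f <- (0:(nseg / 2 - 1)) * fs / nseg
  f[which.max(pw)]
}

# FFT amplitude of the component nearest to f0 (for filter gain checks).
fft_amp <- function(x, fs, f0) {
  n <- length(x)
  a <- Mod(stats::fft(x))[1:(n %/% 2)] * 2 / n
  f <- (0:(n %/% 2 - 1)) * fs / n
  a[which.min(abs(f - f0))]
}

# Floyd-Warshall distances under the (target, source) adjacency convention:
# adj[i, j] = 1 is an edge j -> i; d[i, j] = shortest path from i to j.
fw_dist <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && adj[i, j] != 0) d[j, i] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

fw_eglob <- function(adj) {
  n <- nrow(adj)
  d <- fw_dist(adj)
  e <- 1 / d
  e[!is.finite(e)] <- 0
  diag(e) <- 0
  sum(e) / (n * (n - 1))
}

fw_eloc <- function(adj) {
  n <- nrow(adj)
  vals <- sapply(seq_len(n), function(i) {
    nb <- which((adj[i, ] != 0 | adj[, i] != 0) & seq_len(n) != i)
    if (length(nb) < 2) return(0)
    fw_eglob(adj[nb, nb, drop = FALSE])
  })
  mean(vals)
}

# Literal per-element evaluation of the spectral transfer matrix and PDC,
# looping over entries and lags.
pdc_direct <- function(coeffs, f, fs) {
  if (is.matrix(coeffs)) coeffs <- array(coeffs, c(1, dim(coeffs)))
  p <- dim(coeffs)[1]; m <- dim(coeffs)[2]
  A <- matrix(0 + 0i, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    s <- 0 + 0i
    for (r in seq_len(p))
      s <- s + coeffs[r, i, j] * exp(-2i * pi * f * r / fs)
    A[i, j] <- (i == j) - s
  }
  P <- matrix(0, m, m)
  for (j in seq_len(m)) {
    cn <- sqrt(sum(Mod(A[, j])^2))
    P[, j] <- Mod(A[, j]) / cn
  }
  P
}

# Random binary directed adjacency with zero diagonal.
rand_adj <- function(n, density) {
  a <- matrix(as.integer(stats::runif(n * n) < density), n, n)
  diag(a) <- 0L
  a
}

# Adjacency of the directed 3-cycle 1 -> 2 -> 3 -> 1 (entry (i,j) = j -> i).
cycle3 <- function() {
  a <- matrix(0L, 3, 3)
  a[2, 1] <- a[3, 2] <- a[1, 3] <- 1L
  a
}

# Small 2-channel order-2 oscillator spec with optional 1 -> 2 coupling,
# used as a generic fitted-corpus source.
osc_pair_spec <- function(c12 = 0) {
  co <- array(0, c(2, 2, 2))
  a1 <- pdcnet::ar2_oscillator(10, 250, 0.8)
  a2 <- pdcnet::ar2_oscillator(20, 250, 0.7)
  co[1, 1, 1] <- a1[1]; co[2, 1, 1] <- a1[2]
  co[1, 2, 2] <- a2[1]; co[2, 2, 2] <- a2[2]
  co[1, 2, 1] <- c12
  pdcnet::coupling_spec(co)
}
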