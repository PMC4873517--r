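#' Down-sample a recording with anti-alias filtering
#'
#' Applies a zero-phase low-pass Butterworth filter with cutoff at
#' `0.4 * target_fs` (order 6, applied forward and backward with
#' [signal::filtfilt()]) and then keeps every `fs / target_fs`-th sample.
#' Zero-phase filtering avoids group delay, so window positions downstream
#' stay aligned with the original time axis.
#'
#' @param rec an [eeg_recording()].
#' @param target_fs desired rate in Hz; must divide `rec$fs` evenly and
#'   exceed 60 Hz so the beta band (up to 30 Hz) stays below Nyquist.
#' @return The down-sampled [eeg_recording()] with
#'   `floor(n_samples / factor)` samples.
#' @export
downsample <- function(rec, target_fs) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (target_fs <= 60)
    stop("target_fs must exceed 60 Hz to keep the beta band (<= 30 Hz) ",
         "below the Nyquist rate")
  factor <- rec$fs / target_fs
  if (abs(factor - round(factor)) > 1e-9)
    stop(sprintf("target_fs (%g) must divide the recording rate (%g) evenly",
                 target_fs, rec$fs))
  factor <- as.integer(round(factor))
  if (factor == 1L) return(rec)
  bf <- signal::butter(6, 0.8 / factor)       # 0.4 * target_fs in (0, fs/2)
  filtered <- t(apply(rec$data, 1, function(ch)
    signal::filtfilt(bf, ch)))
  idx <- seq(1L, ncol(rec$data), by = factor)
  out <- eeg_recording(filtered[, idx, drop = FALSE], fs = target_fs,
                       channel_labels = rec$channel_labels,
                       subject_id = rec$subject_id, condition = rec$condition)
  attr(out, "seed") <- attr(rec, "seed")
  attr(out, "spec_description") <- attr(rec, "spec_description")
  attr(out, "ground_truth") <- attr(rec, "ground_truth")
  out
}

#' Cut a recording into sliding analysis windows
#'
#' Window `k` (0-based) starts at sample `k * hop + 1` with
#' `hop = round(window_samples * (1 - overlap_frac))`; a trailing partial
#' window is discarded.
#'
#' @param rec an [eeg_recording()].
#' @param window_s window length in seconds (default 2).
#' @param overlap_frac fractional overlap between consecutive windows in
#'   `[0, 1)` (default 0.5).
#' @return An object of class `window_set`: list with `windows` (list of
#'   channels x window_samples matrices), `window_s`, `overlap_frac`, `fs`,
#'   `hop`, `channel_labels` and `parent_id`.
#' @export
slide_windows <- function(rec, window_s = 2, overlap_frac = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (overlap_frac < 0 || overlap_frac >= 1)
    stop("overlap_frac must be in [0, 1)")
  w <- as.integer(round(window_s * rec$fs))
  n <- ncol(rec$data)
  if (n < w)
    stop(sprintf("recording (%d samples) shorter than one window (%d)", n, w))
  hop <- max(1L, as.integer(round(w * (1 - overlap_frac))))
  n_win <- (n - w) %/% hop + 1L
  windows <- lapply(seq_len(n_win) - 1L, function(k)
    rec$data[, k * hop + seq_len(w), drop = FALSE])
  structure(list(windows = windows, window_s = window_s,
                 overlap_frac = overlap_frac, fs = rec$fs, hop = hop,
                 channel_labels = rec$channel_labels,
                 parent_id = paste(rec$subject_id, rec$condition, sep = "/")),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows of %g s (%d samples, hop %d) @ %g Hz from %s\n",
              length(x$windows), x$window_s, ncol(x$windows[[1]]), x$hop,
              x$fs, x$parent_id))
  invisible(x)
}

#' Conventional clinical EEG rhythm band edges (Hz)
#'
#' Half-open intervals `[lo, hi)`: delta 1-4, theta 4-8, alpha 8-13,
#' beta 13-30.
#'
#' @return Named list of `c(lo, hi)` pairs.
#' @export
band_edges <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30))
}

#' Label frequencies with their EEG rhythm band
#'
#' @param freqs numeric frequencies in Hz.
#' @param edges band definition as from [band_edges()].
#' @return Character vector: `"delta"`, `"theta"`, `"alpha"`, `"beta"` or
#'   `"none"` for frequencies outside every band.
#' @export
band_membership <- function(freqs, edges = band_edges()) {
  out <- rep("none", length(freqs))
  for (b in names(edges))
    out[freqs >= edges[[b]][1] & freqs < edges[[b]][2]] <- b
  out
}

#' Uniform frequency grid with rhythm-band labels
#'
#' Grid points `f_k = k * (fs/2) / n_freqs`, `k = 1..n_freqs`, spanning
#' `(0, fs/2]`; each point is labeled with its band under [band_edges()].
#' Note that for every band to receive at least one grid point the spacing
#' must resolve the narrowest band (delta, 3 Hz wide), i.e.
#' `n_freqs >= fs / 6` roughly; the pipeline default grid
#' ([default_freq_grid()]) uses 0.5 Hz spacing instead.
#'
#' @param fs sampling rate in Hz.
#' @param n_freqs number of grid points (>= 16).
#' @return Data frame with columns `freq` and `band`.
#' @export
band_grid <- function(fs, n_freqs) {
  stopifnot(n_freqs >= 16)
  freqs <- seq_len(n_freqs) * (fs / 2) / n_freqs
  data.frame(freq = freqs, band = band_membership(freqs),
             stringsAsFactors = FALSE)
}

#' Default analysis frequency grid: 0.5 to 30 Hz in 0.5-Hz steps
#'
#' Resolves the narrowest rhythm band with at least 6 grid points while
#' staying inside the 0.05-30 Hz acquisition band.
#'
#' @return Numeric vector of frequencies in Hz.
#' @export
default_freq_grid <- function() seq(0.5, 30, by = 0.5)
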