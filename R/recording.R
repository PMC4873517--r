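#' EEG recording container
#'
#' A labeled multichannel time series together with its sampling rate and a
#' condition tag. This is the object every pipeline stage consumes: rows are
#' channels (in the order of `channel_labels`), columns are samples.
#'
#' @param data numeric matrix, channels x samples; all values must be finite.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_labels character vector of channel names (10-20-system
#'   names for scalp EEG), one per row of `data`.
#' @param subject_id subject identifier.
#' @param condition mental-state tag, one of `"play"` or `"rest"`.
#'
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_labels,
                          subject_id = "S01", condition = c("play", "rest")) {
  condition <- match.arg(condition)
  data <- as.matrix(data)
  if (!is.numeric(data) || anyNA(data) || !all(is.finite(data)))
    stop("recording data must be a finite numeric matrix")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number")
  channel_labels <- as.character(channel_labels)
  if (nrow(data) != length(channel_labels))
    stop("number of data rows (", nrow(data), ") does not match number of ",
         "channel labels (", length(channel_labels), ")")
  rownames(data) <- channel_labels
  structure(
    list(data = data, fs = fs, channel_labels = channel_labels,
         subject_id = as.character(subject_id), condition = condition),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s, condition %s\n", x$subject_id,
              x$condition))
  cat(sprintf("  %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat("  channels:", paste(x$channel_labels, collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

#' Write a recording as CSV plus a JSON sidecar
#'
#' The CSV dialect is one header row of channel labels and one column per
#' channel (samples as rows); values are written with 10 significant digits.
#' The sidecar `<path>.json` records subject id, condition, sampling rate and,
#' when present, the seed and generator description attached to a synthetic
#' recording.
#'
#' @param rec an [eeg_recording()].
#' @param path CSV output path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  df <- as.data.frame(t(rec$data))
  names(df) <- rec$channel_labels
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(subject_id = rec$subject_id, condition = rec$condition,
               fs = rec$fs)
  if (!is.null(attr(rec, "seed"))) side$seed <- attr(rec, "seed")
  if (!is.null(attr(rec, "spec_description")))
    side$spec <- attr(rec, "spec_description")
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path CSV path with a `<path>.json` sidecar.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("missing JSON sidecar for ", path,
         " (expected ", basename(sidecar), ")")
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0L) stop("empty or truncated recording file: ", path)
  if (anyNA(df)) stop("non-finite or missing samples in ", path)
  eeg_recording(t(as.matrix(df)), fs = side$fs,
                channel_labels = names(df),
                subject_id = side$subject_id, condition = side$condition)
}

#' Standard 16-electrode 10-20 montage labels
#'
#' The scalp montage of a 16-channel clinical EEG cap (linked-earlobe
#' reference): frontopolar, frontal, central, parietal, occipital and
#' temporal sites.
#'
#' @return Character vector of 16 electrode labels.
#' @export
montage_1020_16 <- function() {
  c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4",
    "O1", "O2", "F7", "F8", "T3", "T4", "T5", "T6")
}
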