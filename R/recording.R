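#' Canonical 10/20 channel labels
#'
#' The 19 scalp electrodes of the International 10/20 system, linked-ear
#' referenced, in the canonical order used throughout the package.
#'
#' @return Character vector of length 19.
#' @export
qeeg_channels <- function() {
  c("FP1", "FP2", "F3", "F4", "F7", "F8", "C3", "C4", "T3", "T4",
    "T5", "T6", "P3", "P4", "O1", "O2", "FZ", "CZ", "PZ")
}

# modern-nomenclature aliases accepted on input (T7 = T3 etc.)
.channel_aliases <- c(T7 = "T3", T8 = "T4", P7 = "T5", P8 = "T6")

#' Normalize a channel label to canonical form
#'
#' Case-insensitive; strips an "EEG " prefix and a "-LE"/"-REF" suffix as
#' written by some acquisition systems; maps the modern labels T7/T8/P7/P8
#' to their 10/20 equivalents T3/T4/T5/T6.
#'
#' @param labels character vector of raw labels.
#' @return Canonical labels; `NA` where no canonical channel matches.
#' @keywords internal
canonical_channel <- function(labels) {
  x <- toupper(trimws(labels))
  x <- sub("^EEG[ _]*", "", x)
  x <- sub("[-_ ](LE|REF|A1A2|AVG)$", "", x)
  hit <- match(x, names(.channel_aliases))
  x[!is.na(hit)] <- .channel_aliases[hit[!is.na(hit)]]
  ifelse(x %in% qeeg_channels(), x, NA_character_)
}

#' Construct an EEG recording
#'
#' Container for a multichannel resting-state EEG time series. Data are held
#' as a channels x samples matrix in microvolts, with the 19 channels of the
#' 10/20 system in canonical order and a linked-ear reference tag.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz.
#' @param channel_labels channel names matching the rows of `data`; any
#'   accepted alias is normalized, and rows are re-ordered canonically.
#' @param subject_id subject identifier.
#' @param reference reference montage tag (only "linked-ears" is supported).
#' @param meta free-form acquisition metadata (list).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_labels = qeeg_channels(),
                          subject_id = NA_character_,
                          reference = "linked-ears", meta = list()) {
  if (!is.matrix(data)) data <- matrix(data, nrow = length(channel_labels))
  if (length(channel_labels) != nrow(data)) {
    stop("channel_labels must match the number of data rows")
  }
  canon <- canonical_channel(channel_labels)
  if (anyNA(canon)) {
    stop("unrecognized channel label(s): ",
         paste(channel_labels[is.na(canon)], collapse = ", "))
  }
  missing <- setdiff(qeeg_channels(), canon)
  if (length(missing)) {
    stop("missing required channel(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(canon)) stop("duplicated channel label(s)")
  data <- data[match(qeeg_channels(), canon), , drop = FALSE]
  rownames(data) <- qeeg_channels()
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) stop("fs must be a positive scalar")
  if (!all(is.finite(data))) stop("non-finite samples in recording")
  structure(
    list(data = data, fs = fs, subject_id = subject_id,
         channel_labels = qeeg_channels(), reference = reference, meta = meta),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject=%s  19 ch x %d samples @ %g Hz (%.1f s), %s\n",
              x$subject_id, ncol(x$data), x$fs, ncol(x$data) / x$fs, x$reference))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec an `eeg_recording`.
#' @return seconds.
#' @export
rec_duration <- function(rec) ncol(rec$data) / rec$fs

# seed scoped to the calling function; caller's RNG stream is restored on exit
local_seed <- function(seed, envir = parent.frame()) {
  withr::local_seed(seed, .local_envir = envir)
}
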