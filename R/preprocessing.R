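#' Artifact-rejection configuration
#'
#' Three transparent rules applied to the continuous (filtered, resampled)
#' record, per channel: an absolute amplitude limit, a sample-to-sample
#' gradient limit, and a flatline (dead-channel) variance floor evaluated
#' over 1-second sliding windows. Violations from any channel are unioned
#' into one per-sample bad mask and padded with context on both sides.
#' Defaults follow common clinical-EEG practice.
#'
#' @param amp_limit absolute amplitude limit, uV (default 100).
#' @param gradient_limit maximum absolute difference between consecutive
#'   samples, uV per sample (default 50).
#' @param flatline_var variance floor over a 1-s window, uV^2 (default 0.1);
#'   windows below it are marked flat.
#' @param pad_s seconds of context marked bad around a violation (default 0.5).
#' @return list of class `artifact_config`.
#' @export
artifact_config <- function(amp_limit = 100, gradient_limit = 50,
                            flatline_var = 0.1, pad_s = 0.5) {
  stopifnot(amp_limit > 0, gradient_limit > 0, flatline_var > 0, pad_s >= 0)
  structure(list(amp_limit = amp_limit, gradient_limit = gradient_limit,
                 flatline_var = flatline_var, pad_s = pad_s),
            class = "artifact_config")
}

#' Mark artifact-contaminated samples on the continuous record
#'
#' @param rec an `eeg_recording` (filtered and resampled).
#' @param cfg an [artifact_config].
#' @return logical vector, one element per sample; `TRUE` = bad.
#' @export
mark_artifacts <- function(rec, cfg = artifact_config()) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(cfg, "artifact_config"))
  x <- rec$data
  n <- ncol(x)
  bad <- rep(FALSE, n)

  # amplitude rule
  bad <- bad | colSums(abs(x) > cfg$amp_limit) > 0

  # gradient rule: mark both samples of an offending difference
  dx <- abs(x[, -1, drop = FALSE] - x[, -n, drop = FALSE])
  gr <- colSums(dx > cfg$gradient_limit) > 0
  bad[-n] <- bad[-n] | gr
  bad[-1] <- bad[-1] | gr

  # flatline rule: variance over 1-s sliding windows below the floor
  w <- round(rec$fs)
  if (n >= w) {
    for (ch in seq_len(nrow(x))) {
      v <- running_var(x[ch, ], w)
      low <- which(v < cfg$flatline_var)   # window start indices
      if (length(low)) {
        idx <- unique(as.vector(outer(low, 0:(w - 1), `+`)))
        bad[idx] <- TRUE
      }
    }
  }

  # pad context around violations
  pad <- round(cfg$pad_s * rec$fs)
  if (pad > 0 && any(bad)) {
    runs <- mask_runs(bad)
    for (i in seq_len(nrow(runs))) {
      bad[max(1, runs$start[i] - pad):min(n, runs$end[i] + pad)] <- TRUE
    }
  }
  bad
}

# sliding-window variance (denominator n) via cumulative sums; O(n)
running_var <- function(x, w) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  i <- seq_len(n - w + 1)
  s <- cs[i + w] - cs[i]
  s2 <- cs2[i + w] - cs2[i]
  pmax(s2 / w - (s / w)^2, 0)
}

# contiguous TRUE runs of a logical mask, 1-based inclusive indices
mask_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Export a bad-sample mask as an interval table
#'
#' Audit view of [mark_artifacts]: contiguous bad stretches as
#' `(start_s, end_s)` half-open intervals.
#'
#' @param mask logical per-sample mask.
#' @param fs sampling rate of the masked recording, Hz.
#' @return data.frame with `start_s`, `end_s`.
#' @export
mask_intervals <- function(mask, fs) {
  runs <- mask_runs(mask)
  data.frame(start_s = (runs$start - 1) / fs, end_s = runs$end / fs)
}

#' Cut non-overlapping 2-second epochs avoiding bad samples
#'
#' Consecutive non-overlapping windows anchored at sample 0; any window
#' containing a bad sample is dropped; retained windows keep temporal order
#' and their original sample offsets. The grid is never re-anchored after a
#' dropped window.
#'
#' @param rec an `eeg_recording`.
#' @param mask logical bad-sample mask (default: none bad).
#' @param epoch_s epoch length, seconds (default 2).
#' @return An `epoch_set`: list with `epochs` (list of channels x samples
#'   matrices), `offsets` (0-based start samples), `n_retained`,
#'   `retained_seconds`, `fs`, `epoch_s`, `n_total_windows`.
#' @export
segment_epochs <- function(rec, mask = NULL, epoch_s = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  len <- round(rec$fs * epoch_s)
  if (abs(len - rec$fs * epoch_s) > 1e-9) {
    stop("fs * epoch_s must be an integer number of samples")
  }
  n <- ncol(rec$data)
  if (is.null(mask)) mask <- rep(FALSE, n)
  stopifnot(length(mask) == n)
  n_win <- n %/% len
  epochs <- list()
  offsets <- integer(0)
  for (k in seq_len(n_win)) {
    i0 <- (k - 1L) * len
    if (any(mask[(i0 + 1):(i0 + len)])) next
    epochs[[length(epochs) + 1L]] <- rec$data[, (i0 + 1):(i0 + len), drop = FALSE]
    offsets <- c(offsets, i0)
  }
  structure(
    list(epochs = epochs, offsets = offsets, n_retained = length(epochs),
         retained_seconds = length(epochs) * epoch_s, fs = rec$fs,
         epoch_s = epoch_s, n_total_windows = n_win,
         subject_id = rec$subject_id),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d/%d epochs of %g s retained (%g s) @ %g Hz\n",
              x$n_retained, x$n_total_windows, x$epoch_s,
              x$retained_seconds, x$fs))
  invisible(x)
}

#' Minimum-duration gate
#'
#' A recording enters spectral analysis only if its artifact-free epochs sum
#' to at least `min_s` seconds (equality passes).
#'
#' @param es an `epoch_set`.
#' @param min_s minimum retained seconds (default 60).
#' @return list with `pass` (logical) and `epoch_set` (unchanged).
#' @export
enforce_min_duration <- function(es, min_s = 60) {
  stopifnot(inherits(es, "epoch_set"))
  list(pass = es$retained_seconds >= min_s, epoch_set = es)
}
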