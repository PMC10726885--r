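#' Clinical EEG frequency bands
#'
#' The five classical bands used for absolute-power analysis: delta
#' (0.5-4 Hz), theta (4-8 Hz), alpha (8-12 Hz), beta (12-25 Hz) and high
#' beta (25-30 Hz). Shared edges are assigned to the lower band, so on the
#' 0.5 Hz analysis grid delta covers [0.5, 4] and every other band
#' (low, high]; the five bands partition all 60 bins of the 0.5-30 Hz grid.
#'
#' @return data.frame with columns `band`, `low_hz`, `high_hz`.
#' @export
eeg_bands <- function() {
  data.frame(
    band = c("delta", "theta", "alpha", "beta", "high_beta"),
    low_hz = c(0.5, 4, 8, 12, 25),
    high_hz = c(4, 8, 12, 25, 30),
    stringsAsFactors = FALSE
  )
}

#' Frequency grid of the spectral analysis
#' @return bin centers 0.5, 1.0, ..., 30.0 Hz.
#' @export
qeeg_freqs <- function() seq(0.5, 30, by = 0.5)

# band membership of frequency bins: edges belong to the lower band, and the
# lowest band is closed at its lower edge so the full grid is covered
band_of <- function(freqs, bands = eeg_bands()) {
  out <- rep(NA_character_, length(freqs))
  for (i in seq_len(nrow(bands))) {
    lo <- bands$low_hz[i]; hi <- bands$high_hz[i]
    inb <- if (i == 1L) freqs >= lo & freqs <= hi else freqs > lo & freqs <= hi
    out[inb] <- bands$band[i]
  }
  out
}

#' Single-epoch periodogram power
#'
#' Plain (untapered) FFT periodogram of one epoch, returned as one-sided
#' absolute power per frequency bin in microvolts squared. A bin-aligned
#' sinusoid of amplitude A lands entirely in its bin with power A^2/2; the
#' sum over the full grid (DC excluded) equals the epoch's population
#' variance (Parseval).
#'
#' @param epoch numeric matrix, channels x samples, or a bare vector for a
#'   single channel. Sample count must equal `fs * epoch_s`.
#' @param fs sampling rate, Hz (default 128).
#' @param epoch_s epoch length in seconds (default 2, giving 0.5 Hz bins).
#' @param max_hz discard bins above this frequency (default 30; use
#'   `fs / 2` for the full grid to Nyquist).
#' @param taper `"none"` (default) or `"hann"`.
#' @return channels x bins matrix of power, columns named by frequency.
#' @export
epoch_power <- function(epoch, fs = 128, epoch_s = 2, max_hz = 30,
                        taper = c("none", "hann")) {
  taper <- match.arg(taper)
  if (!is.matrix(epoch)) epoch <- matrix(epoch, nrow = 1)
  n <- ncol(epoch)
  if (n != round(fs * epoch_s)) {
    stop(sprintf("epoch must have fs * epoch_s = %d samples, got %d",
                 round(fs * epoch_s), n))
  }
  if (taper == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
    w <- w / sqrt(mean(w^2))  # preserve total power
    epoch <- sweep(epoch, 2, w, `*`)
  }
  X <- t(stats::mvfft(t(epoch)))
  half <- n %/% 2
  p <- (2 / n^2) * Mod(X[, 1 + seq_len(half), drop = FALSE])^2
  p[, half] <- p[, half] / 2  # Nyquist bin is not doubled
  freqs <- seq_len(half) / epoch_s
  keep <- freqs <= max_hz + 1e-9
  p <- p[, keep, drop = FALSE]
  colnames(p) <- as.character(freqs[keep])
  rownames(p) <- rownames(epoch)
  p
}

#' Epoch-averaged absolute power spectrum
#'
#' Arithmetic mean of single-epoch periodograms over the retained epochs of
#' an [epoch_set], on the 0.5-30 Hz grid, together with the per-channel
#' split-half and test-retest reliability of the power estimates and the
#' reliability-gate outcome.
#'
#' @param es an `epoch_set` (see [segment_epochs]).
#' @param reliability_threshold gate: every channel needs both reliabilities
#'   strictly above this (default 0.90).
#' @param taper passed to [epoch_power].
#' @return A `spectral_result`: list with `power` (19 x 60 matrix, uV^2),
#'   `freqs`, `n_epochs_used`, `reliability` (data.frame), `qc_pass`.
#' @export
mean_power <- function(es, reliability_threshold = 0.90, taper = "none") {
  stopifnot(inherits(es, "epoch_set"))
  if (es$n_retained == 0L) stop("no retained epochs: cannot compute spectrum")
  per <- epoch_powers(es, taper = taper)
  pw <- apply(per, c(1, 2), mean)
  sh <- half_reliability(per, split = "odd_even")
  tr <- half_reliability(per, split = "temporal")
  rel <- data.frame(channel = rownames(pw),
                    split_half = sh, test_retest = tr,
                    row.names = NULL, stringsAsFactors = FALSE)
  res <- structure(
    list(power = pw, freqs = qeeg_freqs(), n_epochs_used = es$n_retained,
         reliability = rel, qc_pass = NA),
    class = "spectral_result"
  )
  res$qc_pass <- reliability_gate(res, threshold = reliability_threshold)
  res
}

# channels x bins x epochs array of single-epoch periodograms
epoch_powers <- function(es, taper = "none") {
  arr <- vapply(
    seq_len(es$n_retained),
    function(i) epoch_power(es$epochs[[i]], fs = es$fs,
                            epoch_s = es$epoch_s, taper = taper),
    matrix(0, nrow(es$epochs[[1]]), length(qeeg_freqs()))
  )
  dimnames(arr)[[1]] <- rownames(es$epochs[[1]])
  arr
}

# Pearson r between mean log10 power spectra of two epoch halves, per channel
half_reliability <- function(per, split = c("odd_even", "temporal")) {
  split <- match.arg(split)
  ne <- dim(per)[3]
  if (ne < 4) stop("reliability needs at least 4 epochs, got ", ne)
  idx <- seq_len(ne)
  a <- if (split == "odd_even") idx[idx %% 2 == 1] else idx[idx <= ne / 2]
  b <- setdiff(idx, a)
  floor_p <- 1e-12  # avoid log of exact zeros for degenerate epochs
  nb <- dim(per)[2]
  r <- vapply(seq_len(dim(per)[1]), function(ch) {
    pa <- log10(pmax(rowMeans(matrix(per[ch, , a], nrow = nb)), floor_p))
    pb <- log10(pmax(rowMeans(matrix(per[ch, , b], nrow = nb)), floor_p))
    if (stats::sd(pa) == 0 || stats::sd(pb) == 0) return(NA_real_)
    stats::cor(pa, pb)
  }, numeric(1))
  names(r) <- dimnames(per)[[1]]
  r
}

#' Split-half reliability of the power spectrum
#'
#' Retained epochs are split into odd- and even-indexed halves (by retained
#' order); per channel, the Pearson correlation between the two halves' mean
#' log10 power spectra (60 bins) is returned. An undefined correlation
#' (constant spectrum) is reported as `NA`, which fails the reliability gate.
#'
#' @param es an `epoch_set` with at least 4 retained epochs.
#' @return named numeric vector, one r per channel.
#' @export
split_half_reliability <- function(es) {
  half_reliability(epoch_powers(es), split = "odd_even")
}

#' Test-retest reliability of the power spectrum
#'
#' Same contract as [split_half_reliability] but comparing the first
#' temporal half of the retained epochs against the second, probing
#' within-session stationarity.
#'
#' @inheritParams split_half_reliability
#' @return named numeric vector, one r per channel.
#' @export
test_retest_reliability <- function(es) {
  half_reliability(epoch_powers(es), split = "temporal")
}

#' Reliability gate
#'
#' A recording passes quality control only if every channel's split-half and
#' test-retest reliability are both strictly greater than the threshold.
#' Undefined (`NA`) reliabilities fail.
#'
#' @param sr a `spectral_result`.
#' @param threshold default 0.90.
#' @return logical scalar.
#' @export
reliability_gate <- function(sr, threshold = 0.90) {
  r <- c(sr$reliability$split_half, sr$reliability$test_retest)
  !anyNA(r) && all(r > threshold)
}

#' @export
print.spectral_result <- function(x, ...) {
  cat(sprintf("<spectral_result> 19 ch x %d bins (0.5-30 Hz), %d epochs, qc_pass=%s\n",
              length(x$freqs), x$n_epochs_used, x$qc_pass))
  cat(sprintf("  min split-half r = %.3f, min test-retest r = %.3f\n",
              min(x$reliability$split_half), min(x$reliability$test_retest)))
  invisible(x)
}

#' Aggregate bin power into band power
#'
#' Band absolute power is the sum of the member bins' power under the
#' edge-down membership rule of [eeg_bands].
#'
#' @param sr a `spectral_result`, or a bare channels x 60 power matrix.
#' @param bands band table as from [eeg_bands]; must partition the grid.
#' @return channels x bands matrix (uV^2), class `band_power`.
#' @export
band_aggregate <- function(sr, bands = eeg_bands()) {
  pw <- if (inherits(sr, "spectral_result")) sr$power else sr
  stopifnot(is.matrix(pw), ncol(pw) == length(qeeg_freqs()))
  memb <- band_of(qeeg_freqs(), bands)
  if (anyNA(memb)) {
    stop("bands do not cover the 0.5-30 Hz grid: unassigned bins at ",
         paste(qeeg_freqs()[is.na(memb)], collapse = ", "))
  }
  out <- vapply(bands$band, function(b) {
    rowSums(pw[, memb == b, drop = FALSE])
  }, numeric(nrow(pw)))
  rownames(out) <- rownames(pw)
  class(out) <- c("band_power", class(out))
  out
}

#' Serialize a spectral result to delimited text + QC JSON
#'
#' Writes `<stem>_power.csv` (channel, frequency_hz, power_uv2 long table)
#' and `<stem>_qc.json` (reliability, epoch count, gate outcome).
#'
#' @param sr a `spectral_result`.
#' @param stem output path stem.
#' @return invisibly, the two file paths.
#' @export
write_spectral_result <- function(sr, stem) {
  long <- data.frame(
    channel = rep(rownames(sr$power), times = length(sr$freqs)),
    frequency_hz = rep(sr$freqs, each = nrow(sr$power)),
    power_uv2 = as.vector(sr$power)
  )
  p1 <- paste0(stem, "_power.csv")
  p2 <- paste0(stem, "_qc.json")
  utils::write.csv(long, p1, row.names = FALSE)
  jsonlite::write_json(
    list(n_epochs_used = sr$n_epochs_used, qc_pass = sr$qc_pass,
         reliability = sr$reliability),
    p2, auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  invisible(c(p1, p2))
}
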