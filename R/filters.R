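# complex frequency response of a rational filter at angular frequencies w
freq_response <- function(b, a, w) {
  e <- function(coef) {
    sapply(seq_along(coef), function(j) coef[j] * exp(-1i * w * (j - 1)))
  }
  num <- rowSums(matrix(e(b), nrow = length(w)))
  den <- rowSums(matrix(e(a), nrow = length(w)))
  num / den
}

# multiply every channel's spectrum by a real, even gain defined on the
# positive half-grid; gain[k] applies to frequency (k-1) * fs / n
apply_gain <- function(data, gain_half) {
  n <- ncol(data)
  k <- 0:(n - 1)
  sym <- pmin(k, n - k)          # mirror index into the half grid
  g <- gain_half[sym + 1]
  X <- stats::mvfft(t(data))
  y <- Re(stats::mvfft(X * g, inverse = TRUE)) / n
  t(y)
}

#' Apply the acquisition-chain filters
#'
#' Zero-phase filtering with a 4th-order Butterworth bandpass and a
#' 2nd-order IIR notch at the mains frequency (Q = 30): each channel's
#' spectrum is multiplied by the squared magnitude response of the designed
#' filters, the response a forward-backward (filtfilt) pass would apply,
#' with no phase distortion. DC is removed exactly by the highpass edge.
#' Matches a clinical acquisition chain: 0.5-70 Hz bandpass, 60 Hz notch.
#'
#' @param rec an `eeg_recording`.
#' @param band bandpass edges in Hz (default `c(0.5, 70)`).
#' @param notch notch center frequency in Hz (default 60); `NULL` disables.
#' @return the filtered `eeg_recording`.
#' @export
apply_acquisition_filters <- function(rec, band = c(0.5, 70), notch = 60) {
  stopifnot(inherits(rec, "eeg_recording"), length(band) == 2, band[1] < band[2])
  if (rec$fs <= 2 * band[2]) {
    stop(sprintf("sampling rate %g Hz too low for a %g Hz bandpass edge",
                 rec$fs, band[2]))
  }
  n <- ncol(rec$data)
  w <- 2 * pi * (0:(n %/% 2)) / n
  bp <- signal::butter(4, band / (rec$fs / 2), type = "pass")
  g <- Mod(freq_response(bp$b, bp$a, w))^2
  if (!is.null(notch)) {
    nt <- notch_biquad(notch, rec$fs, q = 30)
    g <- g * Mod(freq_response(nt$b, nt$a, w))^2
  }
  rec$data <- apply_gain(rec$data, g)
  rec$meta$filters <- list(band = band, notch = notch)
  rec
}

# RBJ-cookbook second-order notch biquad
notch_biquad <- function(f0, fs, q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Down-sample a recording
#'
#' Integer-factor decimation after a zero-phase FIR anti-alias filter
#' (Hamming-windowed, order 64, cutoff at the target Nyquist) applied as
#' its exact zero-phase frequency response. The standard step from the
#' 256 Hz acquisition rate to the 128 Hz analysis rate; the output sample
#' count is `floor(n * target_fs / fs)`.
#'
#' @param rec an `eeg_recording`.
#' @param target_fs target sampling rate, Hz (default 128). Must be an
#'   integer divisor of `rec$fs`; up-sampling is an error.
#' @return the down-sampled `eeg_recording`.
#' @export
resample_recording <- function(rec, target_fs = 128) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (target_fs >= rec$fs) {
    if (target_fs == rec$fs) return(rec)
    stop("up-sampling is not supported (target_fs >= fs)")
  }
  q <- rec$fs / target_fs
  if (abs(q - round(q)) > 1e-9) {
    stop("target_fs must divide fs exactly (integer decimation)")
  }
  q <- round(q)
  b <- as.numeric(signal::fir1(64, 1 / q))
  n <- ncol(rec$data)
  w <- 2 * pi * (0:(n %/% 2)) / n
  # linear-phase FIR with the delay compensated: real, even response
  g <- Re(freq_response(b, 1, w) * exp(1i * w * 32))
  filtered <- apply_gain(rec$data, g)
  idx <- seq(1, by = q, length.out = floor(n / q))
  rec$data <- filtered[, idx, drop = FALSE]
  rec$fs <- target_fs
  rec
}
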