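# Minimal EDF (European Data Format) support: continuous 16-bit recordings,
# one data-record per second. Covers what this pipeline needs -- 19 EEG
# signals in physical microvolts -- not the full EDF+ annotation spec.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to EDF
#'
#' 16-bit EDF with 1-second data records and physical units of microvolts.
#' Samples are quantized onto a symmetric digital range spanning the
#' per-channel absolute maximum, so the round-trip error is bounded by half
#' a quantization step. Trailing samples that do not fill a whole data
#' record are dropped.
#'
#' @param rec an `eeg_recording` with integer `fs`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- round(rec$fs)
  if (abs(fs - rec$fs) > 1e-9) stop("EDF writer requires an integer sampling rate")
  ns <- nrow(rec$data)
  n_rec <- ncol(rec$data) %/% fs
  if (n_rec < 1) stop("recording shorter than one EDF data record (1 s)")
  x <- rec$data[, seq_len(n_rec * fs), drop = FALSE]

  pmax_ch <- pmax(apply(abs(x), 1, max), 1e-6)
  dig_max <- 32767
  scale <- pmax_ch / dig_max

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(edf_pad("0", 8), con, eos = NULL)
  writeChar(edf_pad(paste("X X X", rec$subject_id), 80), con, eos = NULL)
  writeChar(edf_pad("Startdate X X X X", 80), con, eos = NULL)
  writeChar(edf_pad("01.01.00", 8), con, eos = NULL)
  writeChar(edf_pad("00.00.00", 8), con, eos = NULL)
  writeChar(edf_pad(256 * (1 + ns), 8), con, eos = NULL)
  writeChar(edf_pad("", 44), con, eos = NULL)
  writeChar(edf_pad(n_rec, 8), con, eos = NULL)
  writeChar(edf_pad(1, 8), con, eos = NULL)
  writeChar(edf_pad(ns, 4), con, eos = NULL)
  for (lab in rownames(x)) writeChar(edf_pad(paste("EEG", lab), 16), con, eos = NULL)
  for (i in seq_len(ns)) writeChar(edf_pad("", 80), con, eos = NULL)
  for (i in seq_len(ns)) writeChar(edf_pad("uV", 8), con, eos = NULL)
  for (i in seq_len(ns)) writeChar(edf_pad(sprintf("%.6g", -pmax_ch[i]), 8), con, eos = NULL)
  for (i in seq_len(ns)) writeChar(edf_pad(sprintf("%.6g", pmax_ch[i]), 8), con, eos = NULL)
  for (i in seq_len(ns)) writeChar(edf_pad(-dig_max, 8), con, eos = NULL)
  for (i in seq_len(ns)) writeChar(edf_pad(dig_max, 8), con, eos = NULL)
  for (i in seq_len(ns)) writeChar(edf_pad("", 80), con, eos = NULL)
  for (i in seq_len(ns)) writeChar(edf_pad(fs, 8), con, eos = NULL)
  for (i in seq_len(ns)) writeChar(edf_pad("", 32), con, eos = NULL)

  dig <- round(sweep(x, 1, scale, `/`))
  dig[dig > dig_max] <- dig_max
  dig[dig < -dig_max] <- -dig_max
  for (r in seq_len(n_rec)) {
    block <- dig[, ((r - 1) * fs + 1):(r * fs), drop = FALSE]
    writeBin(as.integer(t(block)), con, size = 2, endian = "little")
  }
  invisible(path)
}

read_edf_impl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd_s <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd_n <- function(w) as.numeric(rd_s(w))
  rd_s(8); rd_s(80); rd_s(80); rd_s(8); rd_s(8)
  rd_n(8); rd_s(44)
  n_rec <- rd_n(8)
  rec_dur <- rd_n(8)
  ns <- as.integer(rd_n(4))
  labels <- vapply(seq_len(ns), function(i) rd_s(16), character(1))
  for (i in seq_len(ns)) rd_s(80)
  dims <- vapply(seq_len(ns), function(i) rd_s(8), character(1))
  phys_min <- vapply(seq_len(ns), function(i) rd_n(8), numeric(1))
  phys_max <- vapply(seq_len(ns), function(i) rd_n(8), numeric(1))
  dig_min <- vapply(seq_len(ns), function(i) rd_n(8), numeric(1))
  dig_max <- vapply(seq_len(ns), function(i) rd_n(8), numeric(1))
  for (i in seq_len(ns)) rd_s(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd_n(8)), integer(1))
  for (i in seq_len(ns)) rd_s(32)

  if (n_rec < 0) stop("EDF header does not state the number of data records")
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  offset <- phys_min - gain * dig_min
  out <- lapply(seq_len(ns), function(i) numeric(n_rec * spr[i]))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      v <- readBin(con, "integer", n = spr[i], size = 2,
                   endian = "little", signed = TRUE)
      out[[i]][((r - 1) * spr[i] + 1):(r * spr[i])] <- gain[i] * v + offset[i]
    }
  }
  list(labels = labels, dims = dims, fs = spr / rec_dur, signals = out)
}

#' Read an EEG recording from disk
#'
#' Supported formats: EDF (16-bit, physical units converted to microvolts;
#' mV and V dimensions are rescaled, unknown units are an error) and the
#' plain-matrix fallback written by [write_matrix_recording] (delimited
#' text, one row per sample, header of channel labels, sampling rate in a
#' JSON sidecar). Channel labels are matched case-insensitively, an
#' "EEG " prefix is ignored, and the modern labels T7/T8/P7/P8 map to
#' T3/T4/T5/T6. All 19 canonical channels must be present; the loaded
#' recording is in canonical channel order.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"edf"` or `"matrix"`.
#' @param subject_id optional subject id to attach.
#' @return an `eeg_recording`.
#' @export
read_recording <- function(path, format = c("auto", "edf", "matrix"),
                           subject_id = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "matrix"
  }
  if (format == "edf") {
    raw <- read_edf_impl(path)
    canon <- canonical_channel(raw$labels)
    keep <- which(!is.na(canon))
    missing <- setdiff(qeeg_channels(), canon[keep])
    if (length(missing)) {
      stop("EDF file is missing required channel(s): ",
           paste(missing, collapse = ", "))
    }
    to_uv <- function(dim) {
      switch(tolower(sub("\\xb5|\\xc2\\xb5", "u", dim, useBytes = TRUE)),
             "uv" = 1, "mv" = 1e3, "v" = 1e6,
             stop("unknown physical dimension in EDF: '", dim, "'"))
    }
    fs <- unique(raw$fs[keep])
    if (length(fs) != 1) stop("EEG channels disagree on sampling rate")
    data <- do.call(rbind, lapply(keep, function(i) raw$signals[[i]] * to_uv(raw$dims[i])))
    eeg_recording(data, fs = fs, channel_labels = canon[keep],
                  subject_id = subject_id)
  } else {
    meta_path <- paste0(path, ".meta.json")
    if (!file.exists(meta_path)) {
      stop("matrix recording needs a sidecar '", meta_path, "' with the sampling rate")
    }
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (is.null(meta$fs)) stop("sidecar does not state fs")
    tab <- utils::read.delim(path, check.names = FALSE)
    eeg_recording(t(as.matrix(tab)), fs = meta$fs, channel_labels = colnames(tab),
                  subject_id = if (!is.null(meta$subject_id)) meta$subject_id else subject_id)
  }
}

#' Write a recording as delimited text (matrix fallback)
#'
#' Tab-delimited, one row per sample, header of channel labels, plus a JSON
#' sidecar `<path>.meta.json` holding the sampling rate and subject id.
#'
#' @param rec an `eeg_recording`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_matrix_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  tab <- as.data.frame(t(rec$data))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(fs = rec$fs, subject_id = rec$subject_id,
                            reference = rec$reference),
                       paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
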