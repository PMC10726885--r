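#' Build an age-stratified normative database
#'
#' For every age bin, channel and band, the mean and standard deviation
#' (n - 1 denominator) of the transformed band power across the reference
#' subjects falling in that bin. Age bins are half-open `[low, high)`
#' intervals, the last bin closed; every bin must receive at least 5
#' subjects and have strictly positive SD in every cell.
#'
#' The default transform is log10: raw absolute power in uV^2 is heavily
#' right-skewed, and the z > 1.96 threshold's "top 2.5%" reading presumes
#' approximate Gaussianity. The identity transform is available for
#' strict raw-power fidelity.
#'
#' @param cohort list of `list(age, band_power)` entries, band_power a
#'   19 x 5 matrix as from [band_aggregate].
#' @param age_breaks numeric vector of bin edges, years (default 5-year
#'   bins over 0-85).
#' @param transform `"log10"` (default) or `"identity"`.
#' @return list of class `normative_db` with `mu` and `sigma`
#'   (bins x channels x bands arrays), `n` per bin, `age_breaks`,
#'   `transform`, `id`.
#' @export
build_normative_db <- function(cohort, age_breaks = seq(0, 85, by = 5),
                               transform = c("log10", "identity")) {
  transform <- match.arg(transform)
  stopifnot(length(cohort) >= 1, length(age_breaks) >= 2)
  ages <- vapply(cohort, function(s) s$age, numeric(1))
  bins <- .age_bin(ages, age_breaks)
  if (anyNA(bins)) {
    stop("subject age(s) outside the age-bin coverage: ",
         paste(round(ages[is.na(bins)], 1), collapse = ", "))
  }
  used <- sort(unique(bins))
  n_bin <- length(age_breaks) - 1
  bands <- eeg_bands()$band
  tf <- if (transform == "log10") function(x) log10(x) else identity
  mu <- array(NA_real_, c(n_bin, 19, 5),
              dimnames = list(.bin_labels(age_breaks), qeeg_channels(), bands))
  sigma <- mu
  n <- integer(n_bin)
  for (b in used) {
    idx <- which(bins == b)
    if (length(idx) < 5) {
      stop("age bin ", .bin_labels(age_breaks)[b], " has only ",
           length(idx), " subject(s); at least 5 required")
    }
    arr <- vapply(idx, function(i) tf(unclass(cohort[[i]]$band_power)),
                  matrix(0, 19, 5))
    mu[b, , ] <- apply(arr, c(1, 2), mean)
    sd_b <- apply(arr, c(1, 2), stats::sd)
    if (any(sd_b <= 0)) {
      stop("zero SD in age bin ", .bin_labels(age_breaks)[b],
           ": degenerate (identical) reference subjects")
    }
    sigma[b, , ] <- sd_b
    n[b] <- length(idx)
  }
  structure(
    list(mu = mu, sigma = sigma, n = n, age_breaks = age_breaks,
         transform = transform,
         id = sprintf("qeegnorm-db-%d-%s", sum(n), transform)),
    class = "normative_db"
  )
}

.age_bin <- function(age, breaks) {
  b <- findInterval(age, breaks, rightmost.closed = TRUE)
  b[age < breaks[1] | age > breaks[length(breaks)]] <- NA_integer_
  b
}

.bin_labels <- function(breaks) {
  paste0("[", breaks[-length(breaks)], ",", breaks[-1], ")")
}

#' @export
print.normative_db <- function(x, ...) {
  pop <- which(x$n > 0)
  cat(sprintf("<normative_db> %s: %d subjects, %d populated age bin(s), transform=%s\n",
              x$id, sum(x$n), length(pop), x$transform))
  for (b in pop) cat(sprintf("  %s years: n=%d\n",
                             .bin_labels(x$age_breaks)[b], x$n[b]))
  invisible(x)
}

#' Z-score a subject's band power against the normative database
#'
#' `z = (X - mu) / sigma` per channel and band, where `X` is the subject's
#' (transformed) band power and `mu`, `sigma` come from the subject's age
#' bin. Ages outside populated bins are an error: no extrapolation.
#'
#' @param bp 19 x 5 band-power matrix (uV^2), as from [band_aggregate].
#' @param age subject age, years.
#' @param db a `normative_db`.
#' @return list of class `zscore_map`: `z` (19 x 5 matrix), `age`, `db_id`,
#'   `threshold_default`.
#' @export
zscore_map <- function(bp, age, db) {
  stopifnot(inherits(db, "normative_db"))
  b <- .age_bin(age, db$age_breaks)
  if (is.na(b) || db$n[b] == 0) {
    stop(sprintf("age %.1f is outside the normative database coverage", age))
  }
  tf <- if (db$transform == "log10") function(x) log10(x) else identity
  z <- (tf(unclass(bp)) - db$mu[b, , ]) / db$sigma[b, , ]
  if (!all(is.finite(z))) stop("non-finite z-scores (zero or negative power?)")
  structure(list(z = z, age = age, db_id = db$id), class = "zscore_map")
}

#' Persist a normative database as a JSON bundle
#'
#' Metadata (transform, bins, n per bin) plus the full mu/sigma table in a
#' versioned, human-readable JSON file; [read_normative_db] validates the
#' invariants on load.
#'
#' @param db a `normative_db`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_normative_db <- function(db, path) {
  stopifnot(inherits(db, "normative_db"))
  payload <- list(
    format = "qeegnorm-db/1", id = db$id, transform = db$transform,
    age_breaks = db$age_breaks, n = db$n,
    channels = qeeg_channels(), bands = eeg_bands()$band,
    dim = dim(db$mu),                 # column-major flattening
    mu = as.vector(db$mu), sigma = as.vector(db$sigma)
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       na = "null")
  invisible(path)
}

#' Load a normative database written by [write_normative_db]
#'
#' @param path JSON path.
#' @return a validated `normative_db`.
#' @export
read_normative_db <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$format) || p$format != "qeegnorm-db/1") {
    stop("not a qeegnorm normative database bundle: ", path)
  }
  dn <- list(.bin_labels(p$age_breaks), p$channels, p$bands)
  db <- structure(
    list(mu = array(p$mu, dim = c(length(p$n), 19, 5), dimnames = dn),
         sigma = array(p$sigma, dim = c(length(p$n), 19, 5), dimnames = dn),
         n = as.integer(p$n), age_breaks = p$age_breaks,
         transform = p$transform, id = p$id),
    class = "normative_db"
  )
  pop <- which(db$n > 0)
  if (!length(pop)) stop("normative database has no populated age bins")
  if (any(db$n[pop] < 5)) stop("normative database has a bin with n < 5")
  for (b in pop) {
    if (any(!is.finite(db$sigma[b, , ])) || any(db$sigma[b, , ] <= 0)) {
      stop("normative database has non-positive sigma in bin ",
           .bin_labels(db$age_breaks)[b])
    }
  }
  db
}
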