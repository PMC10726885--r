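# Synthetic resting-state EEG with a controlled spectrum: 1/f background,
# posterior-dominant alpha, per-band/per-channel log-power offsets expressed
# in normative-SD units, and injectable artifacts. The generator is built in
# the spectral domain (amplitude ~ f^(-beta/2), random phases) so the target
# spectrum is exact up to sampling noise.

default_alpha_weights <- function() {
  w <- stats::setNames(rep(0.3, 19), qeeg_channels())
  w[c("O1", "O2")] <- 1
  w[c("P3", "P4", "PZ")] <- 0.8
  w[c("T5", "T6")] <- 0.6
  w[c("C3", "C4", "CZ")] <- 0.45
  w
}

#' EEG simulation specification
#'
#' Parameters of one synthetic resting-state recording. The spectrum of each
#' channel is `background_scale / f^background_slope` plus a Gaussian alpha
#' bump (0.8 Hz width) weighted toward posterior channels, multiplied within
#' each clinical band by `10^(trend + subject_effect + offset * sd_log)`
#' where the offset is expressed in normative-SD units of log10 band power.
#' Fixed smooth age trends (declining delta/theta with maturation, declining
#' alpha with adult age) make age stratification of the normative database
#' non-trivial.
#'
#' @param duration_s recording length, seconds (default 300, i.e. the
#'   standard 5-minute eyes-closed resting recording).
#' @param fs sampling rate, Hz (default 256). Must exceed 60 Hz.
#' @param background_slope 1/f exponent beta of the background (default 1.5,
#'   typical of eyes-closed resting EEG).
#' @param background_scale background power density at 1 Hz, uV^2/Hz
#'   (default 30).
#' @param alpha_peak list with `center` (Hz), `amplitude` (uV^2/Hz at the
#'   posterior maximum) and optional `weights` (named per-channel vector).
#' @param band_offsets per-band log-power elevation in normative-SD units:
#'   a named list/vector over bands (`delta`, `theta`, `alpha`, `beta`,
#'   `high_beta`); each element a scalar (all channels) or a named
#'   per-channel vector. Unknown band or channel names are an error.
#' @param sd_log the normative SD of log10 band power that offsets are
#'   expressed in, log10 units (default 0.25; must match the inter-subject
#'   spread used for the normative cohort for offsets to be calibrated).
#' @param subject_sd SD of the per-cell (channel x band) inter-subject
#'   log10-power effect drawn internally from the seed (default 0:
#'   deterministic spectrum).
#' @param age subject age in years, drives the fixed trends (default 40).
#' @param artifact_plan list of artifact descriptors, each a list with
#'   `kind` ("blink", "muscle" or "flatline"), `onset_s`, `duration_s`,
#'   `amplitude_uv` (ignored for flatline).
#' @param seed integer RNG seed.
#' @return list of class `eeg_sim_spec`.
#' @export
eeg_sim_spec <- function(duration_s = 300, fs = 256, background_slope = 1.5,
                         background_scale = 30,
                         alpha_peak = list(center = 10, amplitude = 12),
                         band_offsets = NULL, sd_log = 0.25, subject_sd = 0,
                         age = 40, artifact_plan = list(), seed = 1) {
  stopifnot(duration_s > 0, fs > 2 * 30, sd_log > 0, subject_sd >= 0)
  if (is.null(alpha_peak$weights)) alpha_peak$weights <- default_alpha_weights()
  offs <- offset_matrix(band_offsets)
  for (a in artifact_plan) {
    if (!a$kind %in% c("blink", "muscle", "flatline")) {
      stop("unknown artifact kind: ", a$kind)
    }
  }
  structure(
    list(duration_s = duration_s, fs = fs, background_slope = background_slope,
         background_scale = background_scale, alpha_peak = alpha_peak,
         band_offsets = offs, sd_log = sd_log, subject_sd = subject_sd,
         age = age, artifact_plan = artifact_plan, seed = as.integer(seed)),
    class = "eeg_sim_spec"
  )
}

# band offsets in any accepted shape -> 19 x 5 matrix (channels x bands)
offset_matrix <- function(band_offsets) {
  bands <- eeg_bands()$band
  m <- matrix(0, 19, 5, dimnames = list(qeeg_channels(), bands))
  if (is.null(band_offsets)) return(m)
  if (is.matrix(band_offsets)) {
    stopifnot(identical(dim(band_offsets), c(19L, 5L)))
    dimnames(band_offsets) <- dimnames(m)
    return(band_offsets)
  }
  bad <- setdiff(names(band_offsets), bands)
  if (length(bad)) stop("offsets requested for unknown band(s): ",
                        paste(bad, collapse = ", "))
  for (b in names(band_offsets)) {
    v <- band_offsets[[b]]
    if (length(v) == 1 && is.null(names(v))) {
      m[, b] <- v
    } else {
      canon <- canonical_channel(names(v))
      if (anyNA(canon)) stop("offsets requested for unknown channel(s): ",
                             paste(names(v)[is.na(canon)], collapse = ", "))
      m[canon, b] <- v
    }
  }
  if (!all(is.finite(m))) stop("band offsets must be finite")
  m
}

# fixed smooth age trends of log10 band power (relative to age 40):
# delta/theta decline steeply through childhood maturation and are almost
# flat in adulthood; alpha declines linearly through adult life
age_trend_matrix <- function(age) {
  bands <- eeg_bands()$band
  t_band <- c(delta = 0.6 * (exp(-age / 6) - exp(-40 / 6)),
              theta = 0.35 * (exp(-age / 8) - exp(-5)),
              alpha = -0.006 * (age - 40),
              beta = 0, high_beta = 0)
  matrix(rep(t_band, each = 19), 19, 5,
         dimnames = list(qeeg_channels(), bands))
}

#' Simulate a resting-state EEG recording
#'
#' Deterministic given the spec (including its seed): the same spec yields
#' bit-identical sample streams. See [eeg_sim_spec] for the generating
#' model.
#'
#' @param spec an [eeg_sim_spec].
#' @return an `eeg_recording` at `spec$fs`; the spec is kept in `$meta$sim_spec`.
#' @export
simulate_eeg <- function(spec) {
  stopifnot(inherits(spec, "eeg_sim_spec"))
  local_seed(spec$seed)
  n <- round(spec$duration_s * spec$fs)
  df <- 1 / spec$duration_s
  nk <- n %/% 2 - 1          # positive-frequency bins below Nyquist
  f <- seq_len(nk) * df

  # inter-subject effects are broadband: adjacent bands correlate (AR(1),
  # rho = 0.7) while the marginal SD stays subject_sd in every cell
  R <- 0.7^abs(outer(1:5, 1:5, `-`))
  subj <- matrix(stats::rnorm(19 * 5, 0, spec$subject_sd), 19, 5) %*%
    chol(R)
  logg <- age_trend_matrix(spec$age) + subj +
    spec$band_offsets * spec$sd_log

  base <- spec$background_scale / pmax(f, 0.5)^spec$background_slope + 0.05
  # band gains extend past the analysis grid (delta below 0.5 Hz, high beta
  # above 30 Hz) so spectral leakage across the grid edges carries the same
  # gain as the band it lands in, keeping band log power lognormal
  memb <- band_of(f)
  memb[f < 0.5] <- "delta"
  memb[f > 30] <- "high_beta"
  ap <- spec$alpha_peak
  bump_shape <- exp(-(f - ap$center)^2 / (2 * 0.8^2))   # 0.8 Hz width

  # box smoothing of the log-gain across band edges (0.6 Hz half-width,
  # comparable to the 2-s epoch leakage kernel), so the little spectral
  # leakage across an edge carries a matching gain and band log power
  # stays lognormal
  h <- max(1L, round(0.6 * spec$duration_s))
  smooth_edges <- function(v) {
    padded <- c(rep(v[1], h), v, rep(v[length(v)], h))
    cs <- cumsum(c(0, padded))
    (cs[(2 * h + 1) + seq_along(v)] - cs[seq_along(v)]) / (2 * h + 1)
  }

  data <- matrix(0, 19, n, dimnames = list(qeeg_channels(), NULL))
  for (ch in seq_len(19)) {
    S <- base + ap$amplitude * ap$weights[qeeg_channels()[ch]] * bump_shape
    S <- S * 10^smooth_edges(logg[ch, memb])
    amp <- (n / 2) * sqrt(2 * S * df)
    phi <- stats::runif(nk, 0, 2 * pi)
    X <- complex(modulus = amp, argument = phi)
    spec_full <- complex(real = rep(0, n))
    spec_full[1 + seq_len(nk)] <- X
    spec_full[n + 1 - seq_len(nk)] <- Conj(X)
    data[ch, ] <- Re(stats::fft(spec_full, inverse = TRUE)) / n
  }

  data <- inject_artifacts(data, spec)
  eeg_recording(data, fs = spec$fs, subject_id = NA_character_,
                meta = list(sim_spec = spec))
}

inject_artifacts <- function(data, spec) {
  fs <- spec$fs
  n <- ncol(data)
  blink_w <- stats::setNames(rep(0.05, 19), qeeg_channels())
  blink_w[c("FP1", "FP2")] <- 1
  blink_w[c("F3", "F4")] <- 0.6
  blink_w[c("F7", "F8")] <- 0.5
  blink_w["FZ"] <- 0.4
  muscle_w <- stats::setNames(rep(0.2, 19), qeeg_channels())
  muscle_w[c("T3", "T4", "F7", "F8")] <- 1
  for (a in spec$artifact_plan) {
    i0 <- round(a$onset_s * fs) + 1
    len <- round(a$duration_s * fs)
    idx <- i0:min(n, i0 + len - 1)
    if (a$kind == "blink") {
      pulse <- a$amplitude_uv * 0.5 * (1 - cos(2 * pi * seq_along(idx) / length(idx)))
      data[, idx] <- data[, idx] + outer(blink_w, pulse)
    } else if (a$kind == "muscle") {
      bp <- signal::butter(4, c(30, min(70, fs / 2 - 1)) / (fs / 2), type = "pass")
      noise <- signal::filtfilt(bp, stats::rnorm(length(idx) + 2 * fs))
      noise <- noise[fs + seq_along(idx)]
      noise <- noise / stats::sd(noise) * a$amplitude_uv / 2
      data[, idx] <- data[, idx] + outer(muscle_w, noise)
    } else if (a$kind == "flatline") {
      data[, idx] <- 0
    }
  }
  data
}

#' Simulate a normative reference cohort
#'
#' Subjects with zero band offsets: inter-subject log-power spread
#' (`subject_sd`) plus the generator's smooth age trends, over ages sampled
#' uniformly on `age_range`. These recordings define the normative database
#' that z-scores are computed against; cohort subjects simulated with zero
#' offsets are exchangeable with them.
#'
#' @param n number of subjects (a single subject is allowed but warned
#'   about: no SD can be estimated from a stratum of one).
#' @param age_range length-2 numeric, years; must span a positive interval.
#' @param seed integer seed; per-subject sub-seeds are derived from it.
#' @param duration_s,fs,subject_sd,sd_log passed to [eeg_sim_spec].
#' @param as `"recordings"` (list of `list(age, recording)`) or `"specs"`
#'   (list of `list(age, spec)`, for memory-lean streaming pipelines).
#' @return list of length `n`; see `as`.
#' @export
simulate_normative_cohort <- function(n, age_range = c(18, 70), seed = 1,
                                      duration_s = 300, fs = 256,
                                      subject_sd = 0.25, sd_log = 0.25,
                                      as = c("recordings", "specs")) {
  as <- match.arg(as)
  stopifnot(n >= 1)
  if (diff(range(age_range)) <= 0) stop("degenerate age range")
  if (n == 1) warning("cohort of size 1: no stratum SD can be estimated")
  local_seed(seed)
  ages <- stats::runif(n, age_range[1], age_range[2])
  seeds <- sample.int(.Machine$integer.max - 1, n)
  lapply(seq_len(n), function(i) {
    sp <- eeg_sim_spec(duration_s = duration_s, fs = fs, age = ages[i],
                       subject_sd = subject_sd, sd_log = sd_log,
                       seed = seeds[i])
    if (as == "specs") list(age = ages[i], spec = sp)
    else list(age = ages[i], recording = simulate_eeg(sp))
  })
}

#' Default clinical-group profiles for cohort simulation
#'
#' Group sizes, demographics, transcranial-Doppler distributions and
#' per-band offset profiles (normative-SD units) for the five study groups:
#' three migraine subtypes (LF-EM, HF-EM, CM), disease controls (DC,
#' occipital neuralgia) and healthy controls (HC). High-beta offsets are
#' ordered LF-EM < HF-EM < CM; the values are simulator configuration tuned
#' so that group-median biomarkers fall in the clinically reported range
#' (supra-threshold high-beta electrode-count medians near 5/6/8, control
#' near 3).
#'
#' @return named list of per-group parameter lists.
#' @export
default_group_profiles <- function() {
  band_vec <- function(d, t, a, b, hb) {
    c(delta = d, theta = t, alpha = a, beta = b, high_beta = hb)
  }
  list(
    `LF-EM` = list(n = 289, age_mean = 38, age_sd = 10, female_frac = 0.651,
                   mfv_meanlog = log(70), mfv_sdlog = 0.19, tcd_coverage = 0.92,
                   offsets = band_vec(0.60, 0.50, 0.10, 0.70, 1.30)),
    `HF-EM` = list(n = 210, age_mean = 37, age_sd = 11, female_frac = 0.724,
                   mfv_meanlog = log(70), mfv_sdlog = 0.19, tcd_coverage = 0.89,
                   offsets = band_vec(0.62, 0.44, 0.12, 0.82, 1.50)),
    `CM` = list(n = 120, age_mean = 42, age_sd = 12, female_frac = 0.733,
                mfv_meanlog = log(69), mfv_sdlog = 0.19, tcd_coverage = 0.88,
                offsets = band_vec(0.60, 0.53, 0.18, 0.87, 1.75)),
    `DC` = list(n = 86, age_mean = 42, age_sd = 10, female_frac = 0.488,
                mfv_meanlog = log(65), mfv_sdlog = 0.21, tcd_coverage = 0.86,
                offsets = band_vec(0.35, 0.11, -0.08, 0.38, 0.75)),
    `HC` = list(n = 15, age_mean = 34, age_sd = 12, female_frac = 0.533,
                mfv_meanlog = NA, mfv_sdlog = NA, tcd_coverage = 0,
                offsets = band_vec(0.46, 0.00, -0.37, 0.23, 0.80))
  )
}

#' Cohort simulation specification
#'
#' @param groups named list of group profiles (see [default_group_profiles]
#'   for the fields and the defaults mirroring the study's structure).
#'   Groups with `n > 0` must carry an `offsets` profile.
#' @param followup_improved,followup_deteriorated named integer vectors
#'   (per migraine subtype) of subjects receiving a post-treatment
#'   recording; defaults 6/17/14 improved and 1/1/1 deteriorated.
#' @param treatment_effect multiplier applied to the band offsets of
#'   improved subjects' post recordings (default 0.5; < 1 = shrinkage).
#' @param deterioration_effect multiplier for deteriorated subjects'
#'   post recordings (default 1.25).
#' @param duration_s,fs,subject_sd,sd_log recording parameters, as in
#'   [eeg_sim_spec].
#' @param seed integer seed.
#' @return list of class `cohort_sim_spec`.
#' @export
cohort_sim_spec <- function(groups = default_group_profiles(),
                            followup_improved = c(`LF-EM` = 6, `HF-EM` = 17, `CM` = 14),
                            followup_deteriorated = c(`LF-EM` = 1, `HF-EM` = 1, `CM` = 1),
                            treatment_effect = 0.5, deterioration_effect = 1.25,
                            duration_s = 300, fs = 256,
                            subject_sd = 0.25, sd_log = 0.25, seed = 1) {
  for (g in names(groups)) {
    gr <- groups[[g]]
    if (gr$n > 0 && is.null(gr$offsets)) {
      stop("group '", g, "' has n > 0 but no band-offset profile")
    }
    if (gr$n < 0) stop("group '", g, "' has negative n")
    if (!is.null(gr$female_frac) &&
        (gr$female_frac < 0 || gr$female_frac > 1)) {
      stop("female_frac must be in [0, 1] for group '", g, "'")
    }
  }
  mig <- Filter(function(g) !is.null(groups[[g]]$offsets),
                intersect(c("LF-EM", "HF-EM", "CM"), names(groups)))
  hb <- vapply(mig, function(g) groups[[g]]$offsets[["high_beta"]], numeric(1))
  if (length(hb) == 3 && !all(diff(hb) >= 0)) {
    stop("migraine high-beta offsets must be ordered LF-EM <= HF-EM <= CM")
  }
  structure(
    list(groups = groups, followup_improved = followup_improved,
         followup_deteriorated = followup_deteriorated,
         treatment_effect = treatment_effect,
         deterioration_effect = deterioration_effect,
         duration_s = duration_s, fs = fs, subject_sd = subject_sd,
         sd_log = sd_log, seed = as.integer(seed)),
    class = "cohort_sim_spec"
  )
}

#' Simulate a clinical cohort
#'
#' Draws per-subject clinical covariates (age, sex, headache-day counts
#' consistent with the subtype definitions, middle-cerebral-artery mean
#' flow velocity with realistic missingness) and assigns each subject its
#' group's band-offset profile. Follow-up subjects get a second recording
#' seed with offsets multiplied by the treatment (or deterioration) factor.
#' Deterministic given the spec seed.
#'
#' @param spec a [cohort_sim_spec].
#' @param recordings if `TRUE`, also simulate and return the EEG recordings
#'   (memory-heavy for large cohorts); by default only the cohort table is
#'   returned and recordings are generated on demand with
#'   [cohort_recording].
#' @return list with `cohort` (data.frame, one row per subject) and, when
#'   requested, `recordings` / `post_recordings` (named by subject id).
#' @export
simulate_cohort <- function(spec, recordings = FALSE) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  local_seed(spec$seed)
  rows <- list()
  for (g in names(spec$groups)) {
    gr <- spec$groups[[g]]
    if (gr$n == 0) next
    is_mig <- g %in% c("LF-EM", "HF-EM", "CM")
    for (i in seq_len(gr$n)) {
      age <- min(75, max(18, stats::rnorm(1, gr$age_mean, gr$age_sd)))
      sex <- if (stats::runif(1) < gr$female_frac) "F" else "M"
      if (g == "LF-EM") {
        mhd <- sample(1:7, 1); hd <- min(31, mhd + sample(0:3, 1))
      } else if (g == "HF-EM") {
        mhd <- sample(8:14, 1); hd <- min(14, mhd + sample(0:3, 1))
      } else if (g == "CM") {
        hd <- sample(15:28, 1); mhd <- sample(8:min(hd, 20), 1)
      } else {
        mhd <- 0; hd <- if (g == "DC") sample(2:20, 1) else 0
      }
      mfv <- NA_real_
      if (!is.na(gr$mfv_meanlog) && stats::runif(1) < gr$tcd_coverage) {
        mfv <- stats::rlnorm(1, gr$mfv_meanlog, gr$mfv_sdlog)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sprintf("%s_%03d", gsub("-", "", g), i),
        group = if (is_mig) "migraine" else g,
        subtype = if (is_mig) g else NA_character_,
        age = age, sex = sex,
        monthly_headache_days = hd, monthly_mhd = mhd,
        mfv_cm_s = mfv, mfv_increased = flag_mfv(mfv),
        stringsAsFactors = FALSE
      )
    }
  }
  cohort <- do.call(rbind, rows)
  cohort$sim_seed <- sample.int(.Machine$integer.max - 1, nrow(cohort))
  cohort$followup <- "none"
  cohort$post_sim_seed <- NA_integer_
  for (st in names(spec$followup_improved)) {
    pick_followup(cohort, st, spec$followup_improved[[st]], "improved") -> cohort
  }
  for (st in names(spec$followup_deteriorated)) {
    pick_followup(cohort, st, spec$followup_deteriorated[[st]], "deteriorated") -> cohort
  }
  nfu <- sum(cohort$followup != "none")
  if (nfu > 0) {
    cohort$post_sim_seed[cohort$followup != "none"] <-
      sample.int(.Machine$integer.max - 1, nfu)
  }
  out <- list(cohort = cohort, spec = spec)
  if (recordings) {
    out$recordings <- lapply(seq_len(nrow(cohort)), function(i) {
      cohort_recording(cohort, i, spec, session = "pre")
    })
    names(out$recordings) <- cohort$subject_id
    fu <- which(cohort$followup != "none")
    out$post_recordings <- lapply(fu, function(i) {
      cohort_recording(cohort, i, spec, session = "post")
    })
    names(out$post_recordings) <- cohort$subject_id[fu]
  }
  out
}

pick_followup <- function(cohort, subtype, k, label) {
  if (is.na(k) || k == 0) return(cohort)
  free <- which(!is.na(cohort$subtype) & cohort$subtype == subtype &
                  cohort$followup == "none")
  if (length(free) < k) {
    stop("not enough ", subtype, " subjects for the requested follow-up count")
  }
  cohort$followup[free[seq_len(k)]] <- label
  cohort
}

#' Regenerate one cohort subject's recording from its stored seed
#'
#' @param cohort the cohort table from [simulate_cohort].
#' @param i row index of the subject.
#' @param spec the same [cohort_sim_spec] that produced the table.
#' @param session `"pre"` (baseline) or `"post"` (follow-up; offsets scaled
#'   by the treatment or deterioration factor).
#' @return an `eeg_recording`.
#' @export
cohort_recording <- function(cohort, i, spec, session = c("pre", "post")) {
  session <- match.arg(session)
  row <- cohort[i, ]
  gname <- if (row$group == "migraine") row$subtype else row$group
  gr <- spec$groups[[gname]]
  offs <- gr$offsets
  seed <- row$sim_seed
  if (session == "post") {
    if (row$followup == "none") stop("subject ", row$subject_id, " has no follow-up")
    fac <- if (row$followup == "improved") spec$treatment_effect else spec$deterioration_effect
    offs <- offs * fac
    seed <- row$post_sim_seed
  }
  sp <- eeg_sim_spec(duration_s = spec$duration_s, fs = spec$fs,
                     band_offsets = as.list(offs), sd_log = spec$sd_log,
                     subject_sd = spec$subject_sd, age = row$age, seed = seed)
  rec <- simulate_eeg(sp)
  rec$subject_id <- row$subject_id
  rec
}
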