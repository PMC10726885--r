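#' Pipeline configuration
#'
#' Collects every analysis constant in one place; defaults equal the
#' clinical protocol values (0.5-70 Hz bandpass, 60 Hz notch, 128 Hz
#' analysis rate, 2-s epochs, 60 s minimum retained duration, reliability
#' threshold 0.90, z threshold 1.96, log10 normative transform). Round-trips
#' through JSON.
#'
#' @param filter_band bandpass edges, Hz.
#' @param notch_hz mains notch frequency, Hz.
#' @param analysis_fs analysis sampling rate after down-sampling, Hz.
#' @param epoch_s epoch length, seconds.
#' @param min_retained_s minimum artifact-free seconds.
#' @param reliability_threshold split-half / test-retest gate.
#' @param z_threshold supra-threshold electrode cut-off.
#' @param taper epoch taper for the spectral stage: `"hann"` (default;
#'   -31 dB sidelobes keep cross-band leakage from biasing and skewing band
#'   power) or `"none"` (plain rectangular FFT).
#' @param transform normative transform, `"log10"` or `"identity"`.
#' @param age_breaks normative age-bin edges, years.
#' @param artifact artifact thresholds, an [artifact_config].
#' @param seed integer seed for the simulation stages.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(filter_band = c(0.5, 70), notch_hz = 60,
                            analysis_fs = 128, epoch_s = 2,
                            min_retained_s = 60,
                            reliability_threshold = 0.90,
                            z_threshold = 1.96,
                            taper = "hann",
                            transform = "log10",
                            age_breaks = seq(0, 85, by = 5),
                            artifact = artifact_config(),
                            seed = 1) {
  structure(
    list(filter_band = filter_band, notch_hz = notch_hz,
         analysis_fs = analysis_fs, epoch_s = epoch_s,
         min_retained_s = min_retained_s,
         reliability_threshold = reliability_threshold,
         z_threshold = z_threshold, taper = taper, transform = transform,
         age_breaks = age_breaks, artifact = artifact,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Strip classes for serialization
#'
#' Recursively converts a `pipeline_config` (or any nested list) to plain
#' lists/vectors so it round-trips through JSON.
#'
#' @param x a config or nested list.
#' @return an unclassed nested list.
#' @export
config_as_list <- function(x) {
  if (is.list(x)) lapply(unclass(x), config_as_list) else x
}

#' Process one recording through the spectral chain
#'
#' Acquisition filters, down-sampling to the analysis rate, artifact
#' marking, 2-s epoching, the minimum-duration gate, epoch-averaged FFT
#' power with reliability gating, and band aggregation.
#'
#' @param rec an `eeg_recording` at the acquisition rate.
#' @param config a [pipeline_config].
#' @return list with `band_power` (19 x 5, `NULL` if excluded), `qc`
#'   (one-row data.frame: retained seconds, reliabilities, gates, exclusion
#'   reason), and `spectrum` (the `spectral_result`, `NULL` if excluded).
#' @export
process_recording <- function(rec, config = pipeline_config()) {
  rec <- apply_acquisition_filters(rec, band = config$filter_band,
                                   notch = config$notch_hz)
  rec <- resample_recording(rec, target_fs = config$analysis_fs)
  mask <- mark_artifacts(rec, config$artifact)
  es <- segment_epochs(rec, mask, epoch_s = config$epoch_s)
  gate <- enforce_min_duration(es, min_s = config$min_retained_s)
  qc <- data.frame(
    subject_id = rec$subject_id, n_epochs = es$n_retained,
    retained_seconds = es$retained_seconds,
    duration_pass = gate$pass, min_split_half = NA_real_,
    min_test_retest = NA_real_, reliability_pass = NA,
    excluded = FALSE, exclusion_reason = NA_character_,
    stringsAsFactors = FALSE
  )
  if (!gate$pass) {
    qc$excluded <- TRUE
    qc$exclusion_reason <- sprintf(
      "retained duration %.1f s below the %g s minimum",
      es$retained_seconds, config$min_retained_s)
    return(list(band_power = NULL, qc = qc, spectrum = NULL))
  }
  sr <- mean_power(es, reliability_threshold = config$reliability_threshold,
                   taper = config$taper)
  qc$min_split_half <- min(sr$reliability$split_half)
  qc$min_test_retest <- min(sr$reliability$test_retest)
  qc$reliability_pass <- sr$qc_pass
  if (!sr$qc_pass) {
    qc$excluded <- TRUE
    qc$exclusion_reason <- sprintf(
      "reliability below %.2f on at least one channel",
      config$reliability_threshold)
    return(list(band_power = NULL, qc = qc, spectrum = sr))
  }
  list(band_power = band_aggregate(sr), qc = qc, spectrum = sr)
}

#' Build a normative database by streaming simulated reference subjects
#'
#' @param n number of reference subjects.
#' @param age_range sampled uniformly, years.
#' @param config a [pipeline_config]; its seed, age bins and transform are
#'   used.
#' @param duration_s recording length per subject, seconds.
#' @return a `normative_db`.
#' @export
build_synthetic_norms <- function(n, age_range = c(18, 70),
                                  config = pipeline_config(),
                                  duration_s = 300) {
  specs <- simulate_normative_cohort(n, age_range, seed = config$seed,
                                     duration_s = duration_s, as = "specs")
  cohort <- lapply(specs, function(s) {
    res <- process_recording(simulate_eeg(s$spec), config)
    if (is.null(res$band_power)) return(NULL)
    list(age = s$age, band_power = res$band_power)
  })
  cohort <- Filter(Negate(is.null), cohort)
  build_normative_db(cohort, age_breaks = config$age_breaks,
                     transform = config$transform)
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' simulate -> preprocess -> spectra -> z-scores -> biomarkers, writing a
#' per-subject QC manifest, the biomarker table, exclusion log and pre/post
#' delta table into `out_dir`. Deterministic given the config and cohort
#' seeds.
#'
#' @param cohort_spec a [cohort_sim_spec].
#' @param db a `normative_db` (e.g. from [build_synthetic_norms]).
#' @param config a [pipeline_config].
#' @param out_dir output directory, created if needed.
#' @return invisibly, a list with `cohort` (table with biomarker columns),
#'   `deltas`, `qc`, `zmaps` (per-subject z-score maps of included
#'   subjects), `out_dir`.
#' @export
run_pipeline <- function(cohort_spec, db, config = pipeline_config(),
                         out_dir = tempfile("qeeg_run_")) {
  stopifnot(inherits(cohort_spec, "cohort_sim_spec"),
            inherits(db, "normative_db"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_cohort(cohort_spec)
  cohort <- sim$cohort
  bands <- eeg_bands()$band
  for (b in bands) {
    cohort[[paste0("mean_z_", b)]] <- NA_real_
    cohort[[paste0("n_over_", b)]] <- NA_integer_
  }
  cohort$included <- FALSE
  qc_rows <- list()
  zmaps <- list()
  deltas <- list()
  for (i in seq_len(nrow(cohort))) {
    rec <- cohort_recording(cohort, i, cohort_spec, session = "pre")
    res <- process_recording(rec, config)
    qc_rows[[i]] <- res$qc
    if (is.null(res$band_power)) next
    zm <- zscore_map(res$band_power, cohort$age[i], db)
    bm <- summarize_biomarkers(zm, threshold = config$z_threshold)
    cohort[i, paste0("mean_z_", bands)] <- bm$mean_z
    cohort[i, paste0("n_over_", bands)] <- bm$n_electrodes_over
    cohort$included[i] <- TRUE
    zmaps[[cohort$subject_id[i]]] <- zm
    if (cohort$followup[i] != "none") {
      post_rec <- cohort_recording(cohort, i, cohort_spec, session = "post")
      post_res <- process_recording(post_rec, config)
      if (!is.null(post_res$band_power)) {
        post_bm <- summarize_biomarkers(
          zscore_map(post_res$band_power, cohort$age[i], db),
          threshold = config$z_threshold)
        deltas[[length(deltas) + 1L]] <- pre_post(
          bm, post_bm, subject_id = cohort$subject_id[i],
          outcome = cohort$followup[i])
      }
    }
  }
  qc <- do.call(rbind, qc_rows)
  delta_tab <- if (length(deltas)) do.call(rbind, deltas) else NULL
  utils::write.csv(qc, file.path(out_dir, "qc_manifest.csv"), row.names = FALSE)
  utils::write.csv(cohort, file.path(out_dir, "biomarker_table.csv"),
                   row.names = FALSE)
  excl <- qc[qc$excluded, c("subject_id", "exclusion_reason")]
  utils::write.csv(excl, file.path(out_dir, "exclusions.csv"), row.names = FALSE)
  if (!is.null(delta_tab)) {
    utils::write.csv(delta_tab, file.path(out_dir, "pre_post_deltas.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(n_subjects = nrow(cohort), n_included = sum(cohort$included),
         n_excluded = sum(qc$excluded), db_id = db$id,
         config = config_as_list(config)),
    file.path(out_dir, "run_manifest.json"),
    auto_unbox = TRUE, digits = NA, na = "null")
  invisible(list(cohort = cohort, deltas = delta_tab, qc = qc,
                 zmaps = zmaps, out_dir = out_dir))
}

med_iqr <- function(x) {
  q <- stats::quantile(x, c(0.5, 0.25, 0.75), na.rm = TRUE)
  sprintf("%.2f (%.2f-%.2f)", q[1], q[2], q[3])
}

#' Generate the three cohort report tables
#'
#' From a completed [run_pipeline] result: (1) group descriptives with
#' migraine-vs-control comparisons (median and 25th-75th percentile for
#' continuous variables by Mann-Whitney, n (%) for categorical by
#' chi-square/Fisher); (2) crude and adjusted (multivariable logistic) odds
#' ratios of migraine vs disease controls for age, sex, increased MFV and
#' the high-beta electrode count; (3) pre/post biomarker changes in
#' clinically improved subjects by Wilcoxon signed-rank. Statistical
#' comparisons are omitted (with a warning) when a group is missing or too
#' small.
#'
#' @param run result of [run_pipeline].
#' @param out_dir where to write `table1_descriptives.csv`,
#'   `table2_odds_ratios.csv`, `table3_pre_post.csv` (default: the run
#'   directory).
#' @return list of the three data.frames (`NULL` where not computable).
#' @export
make_reports <- function(run, out_dir = run$out_dir) {
  cohort <- run$cohort[run$cohort$included, , drop = FALSE]
  bands <- eeg_bands()$band
  is_mig <- cohort$group == "migraine"
  groups <- split(seq_len(nrow(cohort)),
                  ifelse(is_mig, "migraine", "control"))
  have_both <- length(groups) == 2 && all(lengths(groups) >= 2)

  cont_row <- function(label, values) {
    r <- data.frame(variable = label, stringsAsFactors = FALSE)
    for (g in names(groups)) r[[g]] <- med_iqr(values[groups[[g]]])
    r$p_value <- if (have_both) {
      a <- values[groups$migraine]; b <- values[groups$control]
      mann_whitney(a[!is.na(a)], b[!is.na(b)])$p_value
    } else NA_real_
    r
  }
  t1 <- list(cont_row("age_years", cohort$age))
  fem <- table(factor(is_mig, c(TRUE, FALSE)),
               factor(cohort$sex == "F", c(TRUE, FALSE)))
  r <- data.frame(variable = "female_n_pct", stringsAsFactors = FALSE)
  for (g in names(groups)) {
    f <- sum(cohort$sex[groups[[g]]] == "F")
    r[[g]] <- sprintf("%d (%.1f)", f, 100 * f / length(groups[[g]]))
  }
  r$p_value <- if (have_both && all(fem > 0)) contingency_test(t(fem))$p_value else NA_real_
  t1 <- c(t1, list(r))
  if (any(!is.na(cohort$mfv_cm_s))) {
    t1 <- c(t1, list(cont_row("mca_mfv_cm_s", cohort$mfv_cm_s)))
  }
  for (b in bands) {
    t1 <- c(t1, list(cont_row(paste0("mean_z_", b), cohort[[paste0("mean_z_", b)]]),
                     cont_row(paste0("n_over_", b), cohort[[paste0("n_over_", b)]])))
  }
  table1 <- do.call(rbind, t1)

  # Table 2: migraine vs disease controls, complete TCD cases
  table2 <- NULL
  dc_idx <- cohort$group == "DC"
  if (any(is_mig) && any(dc_idx)) {
    sub <- cohort[(is_mig | dc_idx), , drop = FALSE]
    sub <- sub[!is.na(sub$mfv_increased), , drop = FALSE]
    outcome <- as.numeric(sub$group == "migraine")
    covs <- data.frame(age = sub$age, female = as.numeric(sub$sex == "F"),
                       mfv_increased = as.numeric(sub$mfv_increased),
                       n_over_high_beta = sub$n_over_high_beta)
    table2 <- tryCatch({
      crude <- do.call(rbind, lapply(names(covs), function(v) {
        fit <- logistic_fit(outcome, covs[v])
        fit$term <- v
        fit$model <- "crude"
        fit
      }))
      adj <- logistic_fit(outcome, covs)
      adj$model <- "adjusted"
      rbind(crude, adj)
    }, error = function(e) {
      warning("odds-ratio table not computable: ", conditionMessage(e))
      NULL
    })
  } else {
    warning("odds-ratio table skipped: need both migraine and DC subjects")
  }

  # Table 3: pre/post changes among improved subjects
  table3 <- NULL
  if (!is.null(run$deltas)) {
    imp <- run$deltas[run$deltas$outcome == "improved", , drop = FALSE]
    if (nrow(imp)) {
      table3 <- do.call(rbind, lapply(bands, function(b) {
        d <- imp[imp$band == b, ]
        data.frame(
          band = b,
          mean_z_pre = med_iqr(d$mean_z_pre),
          mean_z_post = med_iqr(d$mean_z_post),
          mean_z_diff = med_iqr(d$mean_z_diff),
          mean_z_p = wilcoxon_signed_rank(d$mean_z_pre, d$mean_z_post)$p_value,
          n_over_pre = med_iqr(d$n_over_pre),
          n_over_post = med_iqr(d$n_over_post),
          n_over_diff = med_iqr(d$n_over_diff),
          n_over_p = wilcoxon_signed_rank(d$n_over_pre, d$n_over_post)$p_value,
          stringsAsFactors = FALSE
        )
      }))
    }
  }

  paths <- list(table1 = table1, table2 = table2, table3 = table3)
  files <- c(table1 = "table1_descriptives.csv",
             table2 = "table2_odds_ratios.csv",
             table3 = "table3_pre_post.csv")
  for (nm in names(paths)) {
    if (!is.null(paths[[nm]])) {
      utils::write.csv(paths[[nm]], file.path(out_dir, files[[nm]]),
                       row.names = FALSE)
    }
  }
  paths
}
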