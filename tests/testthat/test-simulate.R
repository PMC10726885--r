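test_that("simulation is deterministic given spec and seed", {
  sp <- eeg_sim_spec(duration_s = 8, seed = 11, subject_sd = 0.25,
                     artifact_plan = list(list(kind = "blink", onset_s = 3,
                                               duration_s = 0.3, amplitude_uv = 200)))
  r1 <- simulate_eeg(sp)
  r2 <- simulate_eeg(sp)
  expect_identical(r1$data, r2$data)
  r3 <- simulate_eeg(eeg_sim_spec(duration_s = 8, seed = 12, subject_sd = 0.25))
  expect_false(identical(r1$data, r3$data))
})

test_that("background periodogram slope matches the requested 1/f exponent", {
  # oracle: least-squares log-log fit on an independent periodogram
  for (beta in c(1, 1.5)) {
    sp <- eeg_sim_spec(duration_s = 300, background_slope = beta,
                       alpha_peak = list(center = 10, amplitude = 0),
                       seed = 21)
    rec <- simulate_eeg(sp)
    pg <- stats::spec.pgram(stats::ts(rec$data[7, ], frequency = 256),
                            plot = FALSE, taper = 0)
    keep <- pg$freq >= 1 & pg$freq <= 30
    fit <- stats::lm(log(pg$spec[keep]) ~ log(pg$freq[keep]))
    expect_lt(abs(-stats::coef(fit)[2] - beta), 0.2)
  }
})

test_that("invalid channels, bands and artifact kinds are rejected", {
  expect_error(eeg_sim_spec(band_offsets = list(gamma = 1)), "unknown band")
  expect_error(eeg_sim_spec(band_offsets = list(high_beta = c(XX9 = 2))),
               "unknown channel")
  expect_error(eeg_sim_spec(artifact_plan = list(list(kind = "spike",
                                                      onset_s = 1,
                                                      duration_s = 1,
                                                      amplitude_uv = 10))),
               "unknown artifact kind")
  expect_error(eeg_sim_spec(band_offsets = list(delta = Inf)), "finite")
})

test_that("a band offset raises that band's log power on the targeted channel", {
  # same seed => identical phases/noise, so the shift is exact in expectation
  base <- eeg_sim_spec(duration_s = 60, seed = 31)
  up <- eeg_sim_spec(duration_s = 60, seed = 31,
                     band_offsets = list(high_beta = c(O1 = 2)))
  bp0 <- band_aggregate(mean_power(segment_epochs(
    resample_recording(apply_acquisition_filters(simulate_eeg(base))))))
  bp1 <- band_aggregate(mean_power(segment_epochs(
    resample_recording(apply_acquisition_filters(simulate_eeg(up))))))
  shift <- log10(bp1["O1", "high_beta"]) - log10(bp0["O1", "high_beta"])
  # 2 SD x sd_log = 0.5 decades, slightly eroded by epoch spectral leakage
  expect_equal(shift, 2 * 0.25, tolerance = 0.12)
  expect_equal(bp1["O2", "high_beta"], bp0["O2", "high_beta"], tolerance = 1e-6)
  expect_equal(bp1["O1", "delta"], bp0["O1", "delta"], tolerance = 1e-3)
})

test_that("normative cohort is reproducible and carries the built-in age trends", {
  c1 <- simulate_normative_cohort(5, c(20, 60), seed = 41, duration_s = 4)
  c2 <- simulate_normative_cohort(5, c(20, 60), seed = 41, duration_s = 4)
  expect_equal(length(c1), 5)
  expect_identical(c1[[3]]$recording$data, c2[[3]]$recording$data)
  expect_error(simulate_normative_cohort(10, c(30, 30), seed = 1),
               "degenerate age range")
  expect_warning(simulate_normative_cohort(1, c(20, 60), seed = 1,
                                           duration_s = 4),
                 "size 1")

  # t-oracle on generator band powers: alpha log-power declines with age
  young <- simulate_normative_cohort(16, c(18, 22), seed = 42,
                                     duration_s = 30, as = "specs")
  old <- simulate_normative_cohort(16, c(66, 70), seed = 43,
                                   duration_s = 30, as = "specs")
  alpha_lp <- function(ss) {
    rec <- simulate_eeg(ss$spec)
    es <- segment_epochs(resample_recording(apply_acquisition_filters(rec)))
    log10(band_aggregate(mean_power(es))["O1", "alpha"])
  }
  tt <- stats::t.test(vapply(young, alpha_lp, numeric(1)),
                      vapply(old, alpha_lp, numeric(1)),
                      alternative = "greater")
  expect_lt(tt$p.value, 0.05)
})

test_that("cohort simulation honours group sizes, subtype rules and follow-up", {
  spec <- cohort_sim_spec(duration_s = 4, seed = 51)
  sim <- simulate_cohort(spec)
  expect_equal(nrow(sim$cohort), 720)            # 619 migraine + 101 controls
  expect_equal(sum(sim$cohort$group == "migraine"), 619)
  tab <- table(sim$cohort$subtype)
  expect_equal(as.integer(tab[c("LF-EM", "HF-EM", "CM")]), c(289L, 210L, 120L))
  mig <- sim$cohort[sim$cohort$group == "migraine", ]
  expect_identical(classify_subtype(mig$monthly_headache_days, mig$monthly_mhd),
                   mig$subtype)
  expect_equal(sum(sim$cohort$followup == "improved"), 37)
  expect_equal(sum(sim$cohort$followup == "deteriorated"), 3)
  # determinism
  sim2 <- simulate_cohort(spec)
  expect_identical(sim$cohort, sim2$cohort)
})

test_that("cohort spec validation rejects inconsistent profiles", {
  gr <- default_group_profiles()
  gr$CM$offsets <- NULL
  expect_error(cohort_sim_spec(groups = gr), "no band-offset profile")
  gr <- default_group_profiles()
  gr$`LF-EM`$offsets["high_beta"] <- 3  # breaks LF <= HF <= CM ordering
  expect_error(cohort_sim_spec(groups = gr), "ordered")
  gr <- default_group_profiles()
  gr$DC$female_frac <- 1.4
  expect_error(cohort_sim_spec(groups = gr), "female_frac")
})

test_that("post-treatment recordings use shrunken offsets", {
  gr <- default_group_profiles()
  for (g in names(gr)) gr[[g]]$n <- 0
  gr$CM$n <- 2
  spec <- cohort_sim_spec(groups = gr,
                          followup_improved = c(`CM` = 1),
                          followup_deteriorated = c(`CM` = 0),
                          treatment_effect = 0.3, duration_s = 4, seed = 61)
  sim <- simulate_cohort(spec)
  i <- which(sim$cohort$followup == "improved")
  pre <- cohort_recording(sim$cohort, i, spec, "pre")
  post <- cohort_recording(sim$cohort, i, spec, "post")
  off_pre <- pre$meta$sim_spec$band_offsets
  off_post <- post$meta$sim_spec$band_offsets
  expect_equal(off_post, off_pre * 0.3)
  j <- setdiff(seq_len(2), i)[1]
  expect_error(cohort_recording(sim$cohort, j, spec, "post"), "no follow-up")
})
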