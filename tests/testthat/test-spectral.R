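test_that("a bin-aligned unit sinusoid lands in its bin with power A^2/2", {
  tt <- (0:255) / 128
  ep <- matrix(rep(sin(2 * pi * 10 * tt), each = 19), 19, 256)
  p <- epoch_power(ep)
  expect_equal(unname(p[1, "10"]), 0.5, tolerance = 1e-10)
  expect_lt(max(p[1, setdiff(colnames(p), "10")]), 1e-20)

  expect_equal(max(abs(epoch_power(matrix(0, 19, 256)))), 0)
  expect_error(epoch_power(matrix(0, 19, 200)), "samples")
})

test_that("Parseval: full-grid power sums to the epoch variance within 1%", {
  withr::local_seed(91)
  for (rep in 1:5) {
    x <- rnorm(256, sd = sqrt(runif(1, 1, 20)))
    p <- epoch_power(matrix(x, 1, 256), max_hz = 64)
    v <- mean(x^2) - mean(x)^2
    expect_equal(sum(p), v, tolerance = 0.01)
  }
})

test_that("mean spectrum is the arithmetic epoch mean", {
  withr::local_seed(92)
  e1 <- matrix(rnorm(19 * 256, sd = 5), 19, 256)
  es_same <- manual_epoch_set(rep(list(e1), 30))
  sr <- mean_power(es_same)
  expect_equal(sr$power, epoch_power(es_same$epochs[[1]]), tolerance = 1e-12)
  expect_equal(sr$n_epochs_used, 30)

  # two epochs with powers p and 3p average to 2p: amplitude sqrt(3) triples power
  e2 <- e1 * sqrt(3)
  sr2 <- mean_power(manual_epoch_set(list(e1, e2, e1, e2)))
  expect_equal(unname(sr2$power), unname(2 * epoch_power(e1)),
               tolerance = 1e-12)
})

test_that("band aggregation follows the edge-down membership rule", {
  mk <- function(freq_hz) {
    pw <- matrix(0, 19, 60, dimnames = list(qeeg_channels(), NULL))
    pw[, which(abs(qeeg_freqs() - freq_hz) < 1e-9)] <- 1
    pw
  }
  expect_equal(unname(band_aggregate(mk(26))[1, ]), c(0, 0, 0, 0, 1))
  expect_equal(unname(band_aggregate(mk(4))[1, ]), c(1, 0, 0, 0, 0))   # edge down
  expect_equal(unname(band_aggregate(mk(0.5))[1, ]), c(1, 0, 0, 0, 0)) # grid start
  expect_equal(unname(band_aggregate(mk(25))[1, ]), c(0, 0, 0, 1, 0))  # beta keeps 25

  # uniform 1 uV^2/bin: band powers = member-bin counts (brute-force oracle)
  ones <- matrix(1, 19, 60)
  counts <- unname(band_aggregate(ones)[1, ])
  oracle <- vapply(seq_len(nrow(eeg_bands())), function(i) {
    b <- eeg_bands()[i, ]
    f <- qeeg_freqs()
    sum(if (i == 1) f >= b$low_hz & f <= b$high_hz else f > b$low_hz & f <= b$high_hz)
  }, numeric(1))
  expect_equal(counts, oracle)
  expect_equal(sum(counts), 60)  # the five bands partition the grid
})

test_that("band aggregation is linear", {
  withr::local_seed(93)
  p1 <- matrix(rexp(19 * 60), 19, 60)
  p2 <- matrix(rexp(19 * 60), 19, 60)
  expect_equal(unclass(band_aggregate(2 * p1 + 3 * p2)),
               unclass(2 * band_aggregate(p1) + 3 * band_aggregate(p2)),
               tolerance = 1e-12)
})

test_that("split-half reliability is 1 for duplicated epochs, errors below 4", {
  withr::local_seed(94)
  e <- matrix(rnorm(19 * 256, sd = 5), 19, 256)
  f <- matrix(rnorm(19 * 256, sd = 3), 19, 256)
  es <- manual_epoch_set(list(e, e, f, f, e, e))  # odd half == even half
  expect_equal(unname(split_half_reliability(es)), rep(1, 19))
  expect_error(split_half_reliability(manual_epoch_set(list(e, f, e))),
               "at least 4")
})

test_that("independent white-noise halves give near-zero expected reliability", {
  withr::local_seed(95)
  rs <- replicate(20, {
    es <- manual_epoch_set(lapply(1:8, function(i) matrix(rnorm(19 * 256), 19, 256)))
    mean(split_half_reliability(es))
  })
  expect_lt(abs(mean(rs)), 0.15)
})

test_that("a mid-recording spectral drift hurts test-retest more than split-half", {
  withr::local_seed(96)
  # second half gains a strong narrowband component: spectral shape changes
  osc <- 8 * sin(2 * pi * 10 * (0:255) / 128)
  epochs <- c(lapply(1:20, function(i) matrix(rnorm(19 * 256, sd = 3), 19, 256)),
              lapply(1:20, function(i) {
                matrix(rnorm(19 * 256, sd = 3), 19, 256) +
                  matrix(rep(osc, each = 19), 19, 256)
              }))
  es <- manual_epoch_set(epochs)
  expect_lt(mean(test_retest_reliability(es)), mean(split_half_reliability(es)))

  # identical temporal halves give r = 1
  half <- lapply(1:10, function(i) matrix(rnorm(19 * 256, sd = 4), 19, 256))
  es2 <- manual_epoch_set(c(half, half))
  expect_equal(unname(test_retest_reliability(es2)), rep(1, 19))
})

test_that("stationary simulated EEG passes the 0.90 gate at full length", {
  ok <- vapply(1:3, function(s) {
    rec <- simulate_eeg(eeg_sim_spec(duration_s = 300, seed = 100 + s,
                                     subject_sd = 0.25))
    rec <- resample_recording(apply_acquisition_filters(rec))
    es <- segment_epochs(rec, mark_artifacts(rec))
    sr <- mean_power(es)
    sr$qc_pass
  }, logical(1))
  expect_true(all(ok))
})

test_that("the reliability gate is strict at the threshold", {
  sr <- structure(list(reliability = data.frame(
    channel = qeeg_channels(),
    split_half = c(0.90, rep(0.95, 18)),   # one channel exactly at 0.90
    test_retest = rep(0.95, 19))), class = "spectral_result")
  expect_false(reliability_gate(sr, 0.90))
  sr$reliability$split_half[1] <- 0.95
  expect_true(reliability_gate(sr, 0.90))
  sr$reliability$test_retest <- rep(1, 19)
  sr$reliability$split_half <- rep(1, 19)
  expect_true(reliability_gate(sr, 0.90))
  sr$reliability$split_half[3] <- NA  # undefined r fails QC
  expect_false(reliability_gate(sr, 0.90))
})

test_that("reliability is invariant to channel order and global power scaling", {
  withr::local_seed(97)
  epochs <- lapply(1:8, function(i) {
    matrix(rnorm(19 * 256, sd = rep(seq(2, 6, length.out = 19), 256)), 19, 256)
  })
  es <- manual_epoch_set(epochs)
  r1 <- split_half_reliability(es)
  es_scaled <- manual_epoch_set(lapply(epochs, function(e) e * 17))
  expect_equal(split_half_reliability(es_scaled), r1, tolerance = 1e-12)
  perm <- sample(19)
  es_perm <- manual_epoch_set(lapply(epochs, function(e) {
    m <- e[perm, ]
    m
  }))
  expect_equal(unname(split_half_reliability(es_perm)), unname(r1[perm]),
               tolerance = 1e-12)
})
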