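test_that("subtype classification follows the headache-day definitions", {
  expect_equal(classify_subtype(7, 7), "LF-EM")
  expect_equal(classify_subtype(10, 8), "HF-EM")
  expect_equal(classify_subtype(16, 9), "CM")
  expect_equal(classify_subtype(14, 14), "HF-EM")
  expect_equal(classify_subtype(16, 7), "LF-EM")  # >= 15 days but < 8 MHD
  expect_equal(classify_subtype(15, 8), "CM")
  expect_error(classify_subtype(NA, 5), "required")
})

test_that("the MFV flag is strict at 70 cm/s and propagates missingness", {
  expect_true(flag_mfv(71))
  expect_false(flag_mfv(70))
  expect_identical(flag_mfv(NA), NA)
  expect_identical(flag_mfv(c(65, 70.01, NA)), c(FALSE, TRUE, NA))
  expect_error(flag_mfv(-3), "positive")
})

test_that("Mann-Whitney exact route matches enumeration worked examples", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)   # 2/20 assignments as extreme

  same <- mann_whitney(c(1, 2), c(1, 2))
  expect_equal(same$p_value, 1)
})

test_that("Mann-Whitney agrees with the enumeration oracle for all small fixtures", {
  withr::local_seed(131)
  fixtures <- c(
    lapply(1:6, function(i) list(x = sample(1:8, sample(2:5, 1), TRUE),
                                 y = sample(1:8, sample(2:5, 1), TRUE))),
    list(list(x = c(1, 1, 2), y = c(1, 2, 2)),       # heavy ties
         list(x = rnorm(5), y = rnorm(5)))
  )
  for (f in fixtures) {
    got <- mann_whitney(f$x, f$y)
    want <- mw_oracle(f$x, f$y)
    expect_equal(got$statistic, want$u)
    expect_equal(got$p_value, want$p)
  }
})

test_that("Mann-Whitney large-sample route tracks the reference implementation", {
  withr::local_seed(132)
  x <- rnorm(40); y <- rnorm(45, 0.4)
  got <- mann_whitney(x, y)
  ref <- stats::wilcox.test(x, y, correct = TRUE)
  expect_equal(got$p_value, ref$p.value, tolerance = 0.02)
})

test_that("Wilcoxon signed-rank matches enumeration worked examples", {
  r <- wilcoxon_signed_rank(c(2, 3, 4, 5, 6), rep(0, 5))
  expect_equal(r$statistic, 15)          # all positive: maximal V
  expect_equal(r$p_value, 2 / 32)        # doubled one-sided 1/32
  expect_equal(wsr_oracle(c(2, 3, 4, 5, 6))$upper_tail, 1 / 32)

  anti <- wilcoxon_signed_rank(c(3, -3, 5, -5), rep(0, 4))
  expect_equal(anti$p_value, 1)

  expect_warning(res <- wilcoxon_signed_rank(rep(1, 4), rep(1, 4)), "zero")
  expect_equal(res$p_value, 1)
})

test_that("Wilcoxon agrees with the sign-pattern oracle for small fixtures", {
  withr::local_seed(133)
  for (rep in 1:8) {
    d <- sample(c(-4:-1, 1:4), sample(3:9, 1), replace = TRUE)
    got <- wilcoxon_signed_rank(d, rep(0, length(d)))
    want <- wsr_oracle(d)
    expect_equal(got$statistic, want$v)
    expect_equal(got$p_value, want$p)
  }
})

test_that("contingency test routes chi-square vs Fisher on expected counts", {
  # published sex-by-group counts: strongly unbalanced
  sex <- rbind(c(428, 191), c(50, 51))
  r <- contingency_test(sex)
  expect_match(r$method, "chi-square")
  expect_lt(r$p_value, 0.001)

  flat <- contingency_test(rbind(c(10, 10), c(10, 10)))
  expect_equal(flat$p_value, 1)

  small <- rbind(c(1, 9), c(9, 1))
  rf <- contingency_test(small)
  expect_match(rf$method, "Fisher")
  expect_equal(rf$p_value, stats::fisher.test(small)$p.value)
  # hypergeometric enumeration oracle for the same table
  p_hyper <- sum(sapply(0:10, function(a) {
    p <- stats::dhyper(a, 10, 10, 10)
    if (p <= stats::dhyper(1, 10, 10, 10) + 1e-12) p else 0
  }))
  expect_equal(rf$p_value, p_hyper, tolerance = 1e-9)

  expect_error(contingency_test(rbind(c(0, 0), c(3, 4))), "margin")
})

test_that("crude OR reproduces the published 2x2 worked examples", {
  sex <- crude_or(rbind(c(428, 191), c(50, 51)))
  expect_equal(round(sex$or, 2), 2.29)
  expect_equal(round(sex$ci_low, 2), 1.49)
  expect_equal(round(sex$ci_high, 2), 3.50)

  mfv <- crude_or(rbind(c(242, 318), c(28, 46)))
  expect_equal(round(mfv$or, 2), 1.25)
  expect_equal(round(mfv$ci_low, 2), 0.76)
  expect_equal(round(mfv$ci_high, 2), 2.06)

  sym <- crude_or(rbind(c(20, 20), c(20, 20)))
  expect_equal(sym$or, 1)
  expect_true(sym$ci_low < 1 && sym$ci_high > 1)

  expect_error(crude_or(rbind(c(0, 5), c(5, 5))), "Haldane")
  expect_silent(crude_or(rbind(c(0, 5), c(5, 5)), haldane = TRUE))
})

test_that("logistic fit on one binary covariate equals the closed-form 2x2 MLE", {
  a <- 40; b <- 25; c <- 15; d <- 30
  outcome <- c(rep(1, a + b), rep(0, c + d))
  x <- c(rep(1, a), rep(0, b), rep(1, c), rep(0, d))
  fit <- logistic_fit(outcome, data.frame(x = x))
  expect_equal(fit$or, (a * d) / (b * c), tolerance = 1e-6)
  ref <- crude_or(rbind(c(a, b), c(c, d)))
  expect_equal(fit$ci_low, ref$ci_low, tolerance = 1e-4)
  expect_equal(fit$ci_high, ref$ci_high, tolerance = 1e-4)
})

test_that("separation and non-variation are hard errors", {
  x <- c(rep(0, 20), rep(1, 20))
  expect_error(logistic_fit(x, data.frame(x = x)), "separation")
  expect_error(logistic_fit(rep(1, 20), data.frame(x = rnorm(20))),
               "outcome does not vary")
})

test_that("logistic Wald CIs achieve nominal coverage under the null", {
  withr::local_seed(134)
  cover <- vapply(1:200, function(i) {
    n <- 400
    outcome <- rbinom(n, 1, 0.5)
    fit <- logistic_fit(outcome, data.frame(x = rnorm(n)))
    fit$ci_low <= 1 && fit$ci_high >= 1
  }, logical(1))
  expect_gte(mean(cover), 0.90)
  expect_lte(mean(cover), 0.99)
})

test_that("the normality screen gates the descriptive convention", {
  withr::local_seed(135)
  rej <- vapply(1:40, function(i) {
    normality_screen(exp(rnorm(100)))$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.9)

  unif <- vapply(1:40, function(i) {
    normality_screen(rnorm(100))$p_value
  }, numeric(1))
  expect_gt(mean(unif), 0.3)  # no systematic rejection under normality

  expect_error(normality_screen(rep(2, 10)), "constant")
  expect_error(normality_screen(c(1, 2)), "3 <= n")
})
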