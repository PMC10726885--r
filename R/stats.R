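#' Classify migraine subtype from monthly headache-day counts
#'
#' Chronic migraine (CM): 15 or more monthly headache days with at least 8
#' migraine headache days (MHD); otherwise high-frequency episodic (HF-EM)
#' with 8-14 MHD; otherwise low-frequency episodic (LF-EM, fewer than 8
#' MHD). Vectorized.
#'
#' @param monthly_headache_days total headache days per month (0-31).
#' @param monthly_mhd migraine headache days per month (0-31).
#' @return character vector: `"LF-EM"`, `"HF-EM"` or `"CM"`.
#' @export
classify_subtype <- function(monthly_headache_days, monthly_mhd) {
  if (anyNA(monthly_headache_days) || anyNA(monthly_mhd)) {
    stop("headache-day counts are required for subtype classification")
  }
  stopifnot(all(monthly_headache_days >= 0 & monthly_headache_days <= 31),
            all(monthly_mhd >= 0 & monthly_mhd <= monthly_headache_days))
  ifelse(monthly_headache_days >= 15 & monthly_mhd >= 8, "CM",
         ifelse(monthly_mhd >= 8 & monthly_mhd <= 14, "HF-EM", "LF-EM"))
}

#' Flag an increased middle-cerebral-artery mean flow velocity
#'
#' `TRUE` iff the MFV strictly exceeds the threshold (70 cm/s); a missing
#' MFV yields `NA` (subject excluded from TCD analyses). Vectorized.
#'
#' @param mfv_cm_s mean flow velocity, cm/s.
#' @param threshold cm/s (default 70).
#' @return logical vector.
#' @export
flag_mfv <- function(mfv_cm_s, threshold = 70) {
  if (any(!is.na(mfv_cm_s) & mfv_cm_s <= 0)) stop("MFV must be positive")
  ifelse(is.na(mfv_cm_s), NA, mfv_cm_s > threshold)
}

new_test_result <- function(statistic, p_value, method, n, extra = list()) {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1))
  structure(c(list(statistic = statistic, p_value = p_value,
                   method = method, n = n), extra),
            class = "qeeg_test_result")
}

#' @export
print.qeeg_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s)\n", x$method,
              x$statistic, x$p_value, paste(x$n, collapse = "/")))
  invisible(x)
}

# exact two-sided tail probability by the doubling convention, capped at 1
.two_sided_exact <- function(stat, dist_values, tol = 1e-9) {
  p_lo <- mean(dist_values <= stat + tol)
  p_hi <- mean(dist_values >= stat - tol)
  min(1, 2 * min(p_lo, p_hi))
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two independent samples. For combined
#' sizes of at most `exact_max` the null distribution of U is enumerated
#' over all group assignments (ties handled by the 1/2-count convention and
#' the doubling two-sided rule); larger samples use the tie-corrected
#' normal approximation with continuity correction.
#'
#' @param x,y numeric samples (each non-empty).
#' @param exact_max enumerate exactly when `length(x) + length(y)` is at
#'   most this (default 12).
#' @return a `qeeg_test_result` with the U statistic of the first sample.
#' @export
mann_whitney <- function(x, y, exact_max = 12) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  nx <- length(x); ny <- length(y); n <- nx + ny
  u_stat <- function(xx, yy) {
    sum(outer(xx, yy, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  u <- u_stat(x, y)
  if (n <= exact_max) {
    comb <- utils::combn(n, nx)
    pool <- c(x, y)
    us <- apply(comb, 2, function(idx) u_stat(pool[idx], pool[-idx]))
    p <- .two_sided_exact(u, us)
    method <- "Mann-Whitney U (exact enumeration)"
  } else {
    r <- rank(c(x, y))
    ties <- table(c(x, y))
    mu <- nx * ny / 2
    sig2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sig2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "Mann-Whitney U (normal approximation, tie-corrected)"
  }
  new_test_result(u, p, method, c(nx, ny))
}

#' Wilcoxon signed-rank test
#'
#' Two-sided paired comparison. Zero differences are dropped; for at most
#' `exact_max` nonzero differences the null distribution of the
#' positive-rank sum V is enumerated over all 2^n sign patterns (average
#' ranks for tied magnitudes); larger samples use the tie-corrected normal
#' approximation with continuity correction. All-zero differences give a
#' defined result with p = 1 and a warning.
#'
#' @param pre,post paired numeric vectors (or pass differences as `pre`
#'   with `post = 0`).
#' @param exact_max enumeration limit on nonzero pairs (default 15).
#' @return a `qeeg_test_result` with the V statistic (positive-rank sum).
#' @export
wilcoxon_signed_rank <- function(pre, post = 0, exact_max = 15) {
  d <- pre - post
  if (!length(d)) stop("no pairs supplied")
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero; p = 1")
    return(new_test_result(0, 1, "Wilcoxon signed-rank (degenerate)", 0))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_max) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    vs <- as.vector(signs %*% r)
    p <- .two_sided_exact(v, vs)
    method <- "Wilcoxon signed-rank (exact enumeration)"
  } else {
    ties <- table(abs(d))
    mu <- n * (n + 1) / 4
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "Wilcoxon signed-rank (normal approximation, tie-corrected)"
  }
  new_test_result(v, p, method, n)
}

#' Chi-square or Fisher test of a 2x2 table
#'
#' Pearson's chi-square without continuity correction by default; falls
#' back to Fisher's exact test whenever any expected cell count is 5 or
#' less (Cochran's rule: the chi-square approximation needs all expected
#' counts comfortably above 5). A zero row or column margin is an error.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return a `qeeg_test_result`; `$method` names the route taken.
#' @export
contingency_test <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(identical(dim(tab), c(2L, 2L)), all(tab >= 0),
            all(tab == round(tab)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero margin in 2x2 table")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected <= 5)) {
    ft <- stats::fisher.test(tab)
    new_test_result(unname(ft$estimate), ft$p.value, "Fisher's exact test",
                    rowSums(tab))
  } else {
    ct <- stats::chisq.test(tab, correct = FALSE)
    new_test_result(unname(ct$statistic), ct$p.value,
                    "Pearson chi-square (no continuity correction)",
                    rowSums(tab))
  }
}

new_or_row <- function(term, est, se, n, method) {
  z <- est / se
  data.frame(
    term = term, coefficient = est, or = exp(est),
    ci_low = exp(est - 1.96 * se), ci_high = exp(est + 1.96 * se),
    p_value = 2 * stats::pnorm(-abs(z)), n = n, method = method,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Crude odds ratio from a 2x2 table
#'
#' `OR = (a d)/(b c)` with the Wald 95% CI
#' `exp(log OR +- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`, the arithmetic behind
#' a published crude-OR column. Orientation: rows = outcome (case, control),
#' columns = exposure (exposed, unexposed), so `a` = exposed cases.
#'
#' @param tab 2x2 matrix of positive counts
#'   (`rbind(c(a, b), c(c, d))`).
#' @param haldane if `TRUE`, add 0.5 to every cell (Haldane-Anscombe
#'   correction), allowing zero cells. Default `FALSE`: a zero cell is an
#'   error suggesting the correction.
#' @return one-row data.frame: `or`, `ci_low`, `ci_high`, `p_value`, ...
#' @export
crude_or <- function(tab, haldane = FALSE) {
  tab <- as.matrix(tab)
  stopifnot(identical(dim(tab), c(2L, 2L)), all(tab >= 0))
  if (any(tab == 0)) {
    if (!haldane) {
      stop("zero cell in 2x2 table; consider the Haldane-Anscombe ",
           "correction (haldane = TRUE)")
    }
    tab <- tab + 0.5
  }
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  est <- log((a * d) / (b * c))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  new_or_row("exposure", est, se, sum(tab), "crude OR (Wald)")
}

#' Multivariable logistic regression with Wald odds ratios
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares,
#' convergence tolerance 1e-8, at most 100 iterations) of a binary outcome
#' on the supplied covariates, complete cases only. Reports, per covariate,
#' the odds ratio per 1-unit increase with its Wald 95% CI and p-value.
#' Perfect separation and non-convergence are errors, not silent results.
#'
#' @param outcome binary vector (0/1 or logical).
#' @param covariates data.frame of numeric/logical/factor covariates (e.g.
#'   age, sex coded female = 1, increased-MFV flag, high-beta
#'   supra-threshold electrode count).
#' @return data.frame, one row per covariate (intercept omitted):
#'   `term`, `coefficient`, `or`, `ci_low`, `ci_high`, `p_value`, `n`.
#' @export
logistic_fit <- function(outcome, covariates) {
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) == length(outcome))
  dat <- cbind(.outcome = as.numeric(outcome), covariates)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nrow(dat) <= ncol(covariates) + 1) {
    stop("not enough complete cases to fit the model")
  }
  if (length(unique(dat$.outcome)) < 2) stop("outcome does not vary")
  fit <- withCallingHandlers(
    stats::glm(.outcome ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        stop("perfect (or quasi-perfect) separation detected: ",
             "odds ratios are not identifiable", call. = FALSE)
      }
      invokeRestart("muffleWarning")
    }
  )
  if (!fit$converged) stop("IRLS did not converge in 100 iterations")
  if (any(fit$fitted.values < 1e-10 | fit$fitted.values > 1 - 1e-10)) {
    stop("perfect (or quasi-perfect) separation detected: ",
         "odds ratios are not identifiable")
  }
  est <- stats::coef(fit)[-1]
  se <- sqrt(diag(stats::vcov(fit)))[-1]
  out <- do.call(rbind, lapply(seq_along(est), function(i) {
    new_or_row(names(est)[i], est[[i]], se[[i]], nrow(dat),
               "multivariable logistic (Wald)")
  }))
  attr(out, "converged") <- fit$converged
  attr(out, "deviance") <- fit$deviance
  out
}

#' Shapiro-Wilk normality screen
#'
#' Gates the descriptive convention: distributions rejected at p < .05 are
#' reported as median (25th-75th percentile) downstream.
#'
#' @param values numeric vector, 3 <= n <= 5000 after NA removal.
#' @return a `qeeg_test_result` with W and p, plus `$normal` (p >= .05).
#' @export
normality_screen <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3 || n > 5000) stop("Shapiro-Wilk requires 3 <= n <= 5000, got ", n)
  if (stats::sd(values) == 0) stop("constant sample: normality undefined")
  sw <- stats::shapiro.test(values)
  new_test_result(unname(sw$statistic), sw$p.value, "Shapiro-Wilk", n,
                  extra = list(normal = sw$p.value >= 0.05))
}
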