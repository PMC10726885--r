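# shared fixtures and independent oracles

# recording with every channel carrying the same signal
flat_recording <- function(x, fs = 128, subject_id = "fix") {
  eeg_recording(matrix(rep(x, each = 19), nrow = 19), fs = fs,
                subject_id = subject_id)
}

# epoch_set built directly from a list of channels x samples matrices,
# bypassing segmentation (for spectral unit tests)
manual_epoch_set <- function(epochs, fs = 128, epoch_s = 2) {
  lab <- qeeg_channels()
  epochs <- lapply(epochs, function(e) {
    rownames(e) <- lab
    e
  })
  structure(
    list(epochs = epochs, offsets = seq_along(epochs) - 1L,
         n_retained = length(epochs),
         retained_seconds = length(epochs) * epoch_s,
         fs = fs, epoch_s = epoch_s, n_total_windows = length(epochs),
         subject_id = "manual"),
    class = "epoch_set"
  )
}

# brute-force Mann-Whitney enumeration oracle: all group assignments
mw_oracle <- function(x, y) {
  nx <- length(x)
  pool <- c(x, y)
  u_of <- function(xx, yy) sum(outer(xx, yy, function(a, b) (a > b) + 0.5 * (a == b)))
  u <- u_of(x, y)
  us <- apply(utils::combn(length(pool), nx), 2,
              function(idx) u_of(pool[idx], pool[-idx]))
  tol <- 1e-9
  list(u = u,
       p = min(1, 2 * min(mean(us <= u + tol), mean(us >= u - tol))))
}

# brute-force Wilcoxon signed-rank oracle: all 2^n sign patterns
wsr_oracle <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), length(d))))
  vs <- as.vector(signs %*% r)
  tol <- 1e-9
  list(v = v,
       p = min(1, 2 * min(mean(vs <= v + tol), mean(vs >= v - tol))),
       upper_tail = mean(vs >= v - tol))
}

# a small normative database built from synthetic band powers (no EEG
# simulation): log10 band power ~ N(mu_cell, sd) iid per cell
toy_norm_db <- function(n = 40, sd = 0.25, age_breaks = c(20, 60), seed = 7) {
  withr::local_seed(seed)
  mu0 <- matrix(log10(20), 19, 5,
                dimnames = list(qeeg_channels(), eeg_bands()$band))
  cohort <- lapply(seq_len(n), function(i) {
    lp <- mu0 + matrix(stats::rnorm(95, 0, sd), 19, 5)
    list(age = stats::runif(1, 20, 60), band_power = 10^lp)
  })
  build_normative_db(cohort, age_breaks = age_breaks)
}

# synthetic z-score map with chosen values
toy_zmap <- function(z, age = 40, db_id = "toy") {
  if (!is.matrix(z)) z <- matrix(z, 19, 5)
  dimnames(z) <- list(qeeg_channels(), eeg_bands()$band)
  structure(list(z = z, age = age, db_id = db_id), class = "zscore_map")
}
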