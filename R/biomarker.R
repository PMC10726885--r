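#' Per-subject QEEG biomarkers
#'
#' Reduces a z-score map to the two clinical biomarkers, per band: the mean
#' z-score over the 19 electrodes, and the number of electrodes whose z
#' strictly exceeds the threshold (1.96, the upper 2.5% of the normative
#' distribution; ties at the threshold are not counted).
#'
#' @param zm a `zscore_map` (see [zscore_map]).
#' @param threshold z threshold (default 1.96).
#' @return data.frame of class `biomarker_summary` with columns `band`,
#'   `mean_z`, `n_electrodes_over`; the threshold, subject age and database
#'   id are kept as attributes.
#' @export
summarize_biomarkers <- function(zm, threshold = 1.96) {
  stopifnot(inherits(zm, "zscore_map"))
  out <- data.frame(
    band = colnames(zm$z),
    mean_z = colMeans(zm$z),
    n_electrodes_over = as.integer(colSums(zm$z > threshold)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(out, class = c("biomarker_summary", "data.frame"),
            threshold = threshold, age = zm$age, db_id = zm$db_id)
}

#' Pre/post-treatment biomarker change
#'
#' Differences are computed as pre minus post, so clinical improvement with
#' falling power shows as a positive difference. Pre and post summaries
#' must share the threshold and normative database.
#'
#' @param pre,post `biomarker_summary` objects for the same subject.
#' @param subject_id subject identifier.
#' @param outcome external clinical outcome label, `"improved"` or
#'   `"deteriorated"` (triggered by a change of at least 50% in headache
#'   frequency or intensity; the label is an input, never computed here).
#' @param interval_days days between the two recordings (optional).
#' @return data.frame of class `pre_post_delta`, one row per band, with
#'   pre/post/difference for both biomarkers.
#' @export
pre_post <- function(pre, post, subject_id = NA_character_,
                     outcome = c("improved", "deteriorated"),
                     interval_days = NA_real_) {
  outcome <- match.arg(outcome)
  stopifnot(inherits(pre, "biomarker_summary"), inherits(post, "biomarker_summary"))
  if (!identical(attr(pre, "threshold"), attr(post, "threshold"))) {
    stop("pre and post summaries use different thresholds")
  }
  if (!identical(attr(pre, "db_id"), attr(post, "db_id"))) {
    stop("pre and post summaries reference different normative databases")
  }
  stopifnot(identical(pre$band, post$band))
  out <- data.frame(
    subject_id = subject_id, band = pre$band,
    mean_z_pre = pre$mean_z, mean_z_post = post$mean_z,
    mean_z_diff = pre$mean_z - post$mean_z,
    n_over_pre = pre$n_electrodes_over, n_over_post = post$n_electrodes_over,
    n_over_diff = pre$n_electrodes_over - post$n_electrodes_over,
    outcome = outcome, interval_days = interval_days,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(out, class = c("pre_post_delta", "data.frame"))
}

#' Group topographic summary
#'
#' Element-wise median z-score at each electrode and band across the
#' subjects of a group: the plotting-ready table behind scalp-map figures.
#'
#' @param group non-empty list of `zscore_map` objects.
#' @return data.frame with `channel` and one median-z column per band.
#' @export
topographic_summary <- function(group) {
  if (length(group) == 0) stop("empty group: no topographic summary")
  arr <- vapply(group, function(zm) {
    stopifnot(inherits(zm, "zscore_map"))
    zm$z
  }, matrix(0, 19, 5))
  med <- apply(arr, c(1, 2), stats::median)
  data.frame(channel = qeeg_channels(), med, row.names = NULL,
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' Fraction of subjects whose biomarker decreased after treatment
#'
#' The proportion (as a percentage) of pre/post deltas with a strictly
#' positive pre-minus-post difference in the chosen band and biomarker.
#'
#' @param deltas non-empty list of `pre_post_delta` objects (or a single
#'   row-bound data.frame of them).
#' @param band band name (default `"high_beta"`).
#' @param biomarker `"n_over"` (electrode count, default) or `"mean_z"`.
#' @return percentage in [0, 100].
#' @export
decrease_fraction <- function(deltas, band = "high_beta",
                              biomarker = c("n_over", "mean_z")) {
  biomarker <- match.arg(biomarker)
  tab <- if (is.data.frame(deltas)) deltas else do.call(rbind, deltas)
  if (is.null(tab) || nrow(tab) == 0) stop("no pre/post deltas supplied")
  tab <- tab[tab$band == band, , drop = FALSE]
  if (nrow(tab) == 0) stop("unknown band: ", band)
  d <- tab[[paste0(biomarker, "_diff")]]
  100 * mean(d > 0)
}
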