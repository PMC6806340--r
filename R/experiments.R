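# Secondary analyses: rest-interval removal, medication response and
# stratified reporting.

#' Remove long resting intervals from a round
#'
#' Detects maximal intervals where the smoothed total gyroscope magnitude
#' (root-sum-square over all six axes of both sensors, smoothed by a moving
#' average) stays below `energy_threshold` for at least `min_rest_s`
#' seconds, deletes those samples from both recordings and concatenates the
#' remainder. Used to test that estimation does not depend on quiescent,
#' assessment-like episodes: the removal is applied to test data only.
#'
#' @param round a [round_record()] (band-pass filtered).
#' @param min_rest_s minimum rest-interval duration to remove, seconds
#'   (default 15).
#' @param energy_threshold magnitude threshold in deg/s (default 10).
#' @param smooth_s moving-average length in seconds (default 1).
#' @return the round with rest intervals removed; attribute `"removed_s"`
#'   reports the deleted duration, and attribute `"empty"` is TRUE when the
#'   whole round was removed (caller should exclude it).
#' @export
remove_rest_intervals <- function(round, min_rest_s = 15,
                                  energy_threshold = 10, smooth_s = 1) {
  stopifnot(inherits(round, "round_record"))
  fs <- round$wrist$sampling_rate_hz
  n <- min(n_samples(round$wrist), n_samples(round$ankle))
  mag <- sqrt(rowSums(round$wrist$axes[seq_len(n), , drop = FALSE]^2) +
              rowSums(round$ankle$axes[seq_len(n), , drop = FALSE]^2))
  k <- max(1L, as.integer(round(smooth_s * fs)))
  sm <- as.numeric(stats::filter(mag, rep(1 / k, k), sides = 2))
  sm[is.na(sm)] <- mag[is.na(sm)]
  below <- sm < energy_threshold
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  drop <- rep(FALSE, n)
  for (j in seq_along(r$lengths)) {
    if (r$values[j] && r$lengths[j] >= min_rest_s * fs)
      drop[starts[j]:ends[j]] <- TRUE
  }
  removed_s <- sum(drop) / fs
  keep <- which(!drop)
  out <- round
  out$wrist$axes <- round$wrist$axes[keep, , drop = FALSE]
  out$ankle$axes <- round$ankle$axes[keep, , drop = FALSE]
  out$duration_s <- length(keep) / fs
  attr(out, "removed_s") <- removed_s
  attr(out, "empty") <- length(keep) == 0L
  out
}

#' Medication-response analysis of model estimates
#'
#' Per subject with both medication states, averages the predicted subscore
#' over pre- and post-medication rounds and tests for a reduction after
#' medication with a paired one-sided Wilcoxon signed-rank test (a paired
#' t-test is available behind `test = "t"`). Results are reported overall
#' and stratified into tremor-dominant subjects (total subscore >= 1 at any
#' assessment) and non-tremor-dominant subjects (0 at all assessments).
#'
#' @param predictions data.frame with `subject_id`, `round_index`, `y_pred`
#'   (e.g. the `records` of a `tremor_eval`).
#' @param rounds per-round metadata table with `med_state` and label items.
#' @param test `"wilcoxon"` (default) or `"t"`.
#' @return list with elements `overall`, `tremor_dominant`,
#'   `non_tremor_dominant`; each holds the per-subject paired means, the
#'   mean reduction and the one-sided p-value (`NA` when fewer than 2 pairs).
#' @export
medication_response <- function(predictions, rounds,
                                test = c("wilcoxon", "t")) {
  test <- match.arg(test)
  if (!any(rounds$med_state == "post_medication"))
    stop("no post-medication rounds in the dataset")
  df <- merge(predictions, rounds, by = c("subject_id", "round_index"))
  df <- df[df$med_state %in% c("pre_medication", "post_medication"), ,
           drop = FALSE]
  agg <- stats::aggregate(y_pred ~ subject_id + med_state, df, mean)
  wide <- stats::reshape(agg, idvar = "subject_id", timevar = "med_state",
                         direction = "wide")
  names(wide) <- sub("^y_pred\\.", "", names(wide))
  wide <- wide[stats::complete.cases(wide), , drop = FALSE]
  if (nrow(wide) < 2L)
    stop("medication response needs at least 2 subjects with both states")
  totals <- target_values(rounds, "total")
  dom_ids <- unique(rounds$subject_id[totals >= 1])
  analyze <- function(w) {
    if (nrow(w) < 2L)
      return(list(n = nrow(w), pairs = w, mean_reduction = NA_real_,
                  p = NA_real_))
    d <- w$pre_medication - w$post_medication
    p <- if (test == "wilcoxon") {
      if (all(d == 0)) 1
      else stats::wilcox.test(w$pre_medication, w$post_medication,
                              paired = TRUE, alternative = "greater",
                              exact = FALSE)$p.value
    } else stats::t.test(w$pre_medication, w$post_medication, paired = TRUE,
                         alternative = "greater")$p.value
    list(n = nrow(w), pairs = w, mean_reduction = mean(d), p = p)
  }
  list(overall = analyze(wide),
       tremor_dominant = analyze(wide[wide$subject_id %in% dom_ids, ,
                                      drop = FALSE]),
       non_tremor_dominant = analyze(wide[!wide$subject_id %in% dom_ids, ,
                                          drop = FALSE]))
}

#' Stratified evaluation metrics
#'
#' Recomputes round-level Pearson r and MAE within each stratum of the
#' chosen grouping; strata with fewer than 3 rounds (or constant values)
#' report `NA` metrics.
#'
#' @param result a `tremor_eval` (its `records` are re-used).
#' @param rounds per-round metadata table carrying the stratum variables
#'   (`sex` for gender; label items for tremor dominance).
#' @param by `"gender"` (alias `"sex"`) or `"tremor_dominance"`.
#' @return data.frame with one row per stratum: `stratum`, `n_rounds`, `r`,
#'   `p`, `mae`.
#' @export
stratified_report <- function(result, rounds,
                              by = c("gender", "sex", "tremor_dominance")) {
  by <- match.arg(by)
  rec <- merge(result$records, rounds, by = c("subject_id", "round_index"))
  if (by %in% c("gender", "sex")) {
    if (!"sex" %in% names(rounds) || all(is.na(rounds$sex)))
      stop("rounds table has no 'sex' stratum labels")
    rec$stratum <- rec$sex
  } else {
    totals <- target_values(rounds, "total")
    dom_ids <- unique(rounds$subject_id[totals >= 1])
    rec$stratum <- ifelse(rec$subject_id %in% dom_ids,
                          "tremor_dominant", "non_tremor_dominant")
  }
  out <- lapply(split(rec, rec$stratum), function(g) {
    ok <- nrow(g) >= 3L && stats::sd(g$y_true) > 0 && stats::sd(g$y_pred) > 0
    met <- if (ok) pearson_r(g$y_true, g$y_pred)
           else list(r = NA_real_, p = NA_real_)
    data.frame(stratum = g$stratum[1], n_rounds = nrow(g),
               r = met$r, p = met$p, mae = mae(g$y_true, g$y_pred),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
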