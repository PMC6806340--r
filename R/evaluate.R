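# Subject-disjoint evaluation protocols: metrics, splits, hyperparameter
# search, held-out and leave-one-subject-out testing.

#' Pearson correlation with p-value
#'
#' Sample Pearson correlation between round-level truths and estimates, with
#' the two-sided p-value from the t-distribution with n-2 degrees of
#' freedom.
#'
#' @param y_true,y_pred equal-length numeric vectors (length >= 3).
#' @return list with elements `r` and `p`.
#' @export
pearson_r <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred))
  if (length(y_true) < 3L) stop("need at least 3 pairs")
  if (stats::sd(y_true) == 0 || stats::sd(y_pred) == 0)
    stop("correlation undefined for a constant sequence")
  ct <- stats::cor.test(y_true, y_pred, method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Mean absolute error
#'
#' @param y_true,y_pred equal-length numeric vectors.
#' @return non-negative scalar.
#' @export
mae <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 1L)
  mean(abs(y_true - y_pred))
}

new_eval_result <- function(protocol, records, target, method, winner = NULL) {
  met <- if (nrow(records) >= 3L &&
             stats::sd(records$y_true) > 0 && stats::sd(records$y_pred) > 0)
    pearson_r(records$y_true, records$y_pred)
  else list(r = NA_real_, p = NA_real_)
  structure(list(protocol = protocol, records = records,
                 pearson_r = met$r, p_value = met$p,
                 mae = mae(records$y_true, records$y_pred),
                 target = target, method = method, winner = winner),
            class = "tremor_eval")
}

#' @export
print.tremor_eval <- function(x, ...) {
  cat(sprintf("<tremor_eval> protocol=%s  method=%s  target=%s\n",
              x$protocol, x$method, x$target))
  cat(sprintf("  %d rounds: r = %.3f (p = %.3g), MAE = %.3f\n",
              nrow(x$records), x$pearson_r, x$p_value, x$mae))
  if (!is.null(x$winner)) {
    cat("  selected configuration:",
        paste(names(x$winner), unlist(x$winner), sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

# Round-level 80/20 train/validation split, stratified by subject where a
# subject has enough rounds; seeded and deterministic.
val_split <- function(rounds, frac = 0.2, seed = 1L) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  val_idx <- integer(0)
  for (s in unique(rounds$subject_id)) {
    idx <- which(rounds$subject_id == s)
    k <- floor(length(idx) * frac + 0.5)
    if (k >= length(idx)) k <- length(idx) - 1L
    if (k > 0L) val_idx <- c(val_idx, sample(idx, k))
  }
  if (!length(val_idx)) val_idx <- sample(nrow(rounds), 1L)
  list(train = rounds[-val_idx, , drop = FALSE],
       val = rounds[val_idx, , drop = FALSE])
}

grid_as_configs <- function(grid, method, seed) {
  if (is.null(grid)) {
    cfg <- if (method == "boosting") boosting_config(seed = seed)
           else lstm_config(seed = seed)
    return(list(cfg))
  }
  if (inherits(grid, "boosting_config") || inherits(grid, "lstm_config"))
    return(list(grid))
  # data.frame grid: order by model size so ties go to the smaller model
  size_col <- intersect(c("n_trees", "n_hidden"), names(grid))[1]
  if (!is.na(size_col)) grid <- grid[order(grid[[size_col]]), , drop = FALSE]
  lapply(seq_len(nrow(grid)), function(i) {
    args <- as.list(grid[i, , drop = FALSE])
    args$seed <- seed
    do.call(if (method == "boosting") boosting_config else lstm_config, args)
  })
}

fit_predict <- function(windows, train_rounds, test_rounds, target, method,
                        config, val_rounds = NULL) {
  fit <- tremor_fit(windows, train_rounds, target = target, method = method,
                    config = config, val_rounds = val_rounds)
  keys <- round_key(test_rounds)
  wtest <- windows[round_key(windows) %in% keys, , drop = FALSE]
  pred <- stats::predict(fit, wtest)
  pred$y_true <- target_values(test_rounds, target)[
    match(round_key(pred), keys)]
  list(fit = fit, pred = pred)
}

# Select the grid configuration maximizing validation r; first (smallest)
# config wins ties. Validation r of a constant prediction counts as -Inf.
select_config <- function(windows, train_rounds, val_rounds, target, method,
                          configs) {
  if (length(configs) == 1L)
    return(list(config = configs[[1]], val_r = NA_real_))
  best <- NULL; best_r <- -Inf
  for (cfg in configs) {
    fp <- fit_predict(windows, train_rounds, val_rounds, target, method, cfg,
                      val_rounds = if (method == "lstm") val_rounds)
    r <- if (stats::sd(fp$pred$y_pred) == 0 || stats::sd(fp$pred$y_true) == 0 ||
             nrow(fp$pred) < 3L) -Inf
         else stats::cor(fp$pred$y_true, fp$pred$y_pred)
    if (r > best_r) { best_r <- r; best <- cfg }
  }
  if (is.null(best)) best <- configs[[1]]
  list(config = best, val_r = best_r)
}

config_summary <- function(cfg) {
  cfg[setdiff(names(cfg), c("seed"))]
}

#' Leave-one-subject-out evaluation
#'
#' One fold per subject: the held-out subject's rounds are the test set; the
#' remaining subjects' rounds are split 80/20 by rounds (stratified by
#' subject, seeded) into training and validation for hyperparameter / epoch
#' selection. Boosting refits the selected configuration on all remaining
#' rounds; the LSTM keeps its best-validation-epoch parameters. Pooled
#' metrics are computed over all folds' test predictions, which partition
#' the dataset's rounds.
#'
#' @param windows per-window feature data.frame (see [extract_features()]).
#' @param rounds per-round metadata table (see [round_table()]).
#' @param target regression target (see [tremor_fit()]).
#' @param method `"boosting"` or `"lstm"`.
#' @param grid hyperparameter grid: `NULL` (back-end defaults), a single
#'   config object, or a data.frame of config columns (e.g.
#'   [default_boosting_grid()]).
#' @param seed integer seed controlling splits and fits.
#' @param progress print one line per fold (default FALSE).
#' @return a `tremor_eval` (pooled) with attribute `"folds"` holding the
#'   per-fold results.
#' @export
run_loso <- function(windows, rounds, target = "total", method = "boosting",
                     grid = NULL, seed = 1L, progress = FALSE) {
  subjects <- unique(rounds$subject_id)
  if (length(subjects) < 3L) stop("LOSO needs at least 3 subjects")
  pooled <- list(); folds <- list()
  for (k in seq_along(subjects)) {
    s <- subjects[k]
    test_rounds <- rounds[rounds$subject_id == s, , drop = FALSE]
    if (nrow(test_rounds) == 0L) {
      warning("subject ", s, " has zero rounds; fold skipped")
      next
    }
    rest <- rounds[rounds$subject_id != s, , drop = FALSE]
    fold_seed <- (seed + 7L * k) %% .Machine$integer.max
    sp <- val_split(rest, frac = 0.2, seed = fold_seed)
    configs <- grid_as_configs(grid, method, fold_seed)
    sel <- select_config(windows, sp$train, sp$val, target, method, configs)
    if (method == "boosting") {
      fp <- fit_predict(windows, rest, test_rounds, target, method, sel$config)
    } else {
      fp <- fit_predict(windows, sp$train, test_rounds, target, method,
                        sel$config, val_rounds = sp$val)
    }
    rec <- fp$pred
    rec$fold <- k
    pooled[[length(pooled) + 1L]] <- rec
    folds[[length(folds) + 1L]] <-
      new_eval_result("loso", rec, target, method,
                      winner = config_summary(sel$config))
    if (progress)
      message(sprintf("fold %d/%d (subject %s): %d test rounds",
                      k, length(subjects), s, nrow(rec)))
  }
  records <- do.call(rbind, pooled)
  out <- new_eval_result("loso", records, target, method)
  attr(out, "folds") <- folds
  out
}

#' Held-out evaluation
#'
#' Trains on the subjects recorded in discrete bouts of daily-living
#' activities (`protocol == "adl_rounds"`) and tests once on the
#' continuously recorded subjects (`protocol == "continuous"`).
#' Hyperparameters are selected by leave-one-subject-out search inside the
#' training partition (maximizing pooled inner-validation r); the winning
#' configuration is refitted on all training subjects. Normalization
#' statistics always come from the training windows only.
#'
#' @inheritParams run_loso
#' @return a `tremor_eval` with the winning configuration recorded.
#' @export
run_held_out <- function(windows, rounds, target = "total",
                         method = "boosting", grid = NULL, seed = 1L) {
  if (!"protocol" %in% names(rounds))
    stop("rounds table must carry a 'protocol' column")
  train_rounds <- rounds[rounds$protocol == "adl_rounds", , drop = FALSE]
  test_rounds <- rounds[rounds$protocol == "continuous", , drop = FALSE]
  if (length(unique(train_rounds$subject_id)) < 2L ||
      length(unique(test_rounds$subject_id)) < 2L)
    stop("need at least 2 subjects in each partition")
  configs <- grid_as_configs(grid, method, seed)
  if (length(configs) > 1L) {
    # inner LOSO over the training subjects
    scores <- vapply(configs, function(cfg) {
      preds <- lapply(unique(train_rounds$subject_id), function(s) {
        tr <- train_rounds[train_rounds$subject_id != s, , drop = FALSE]
        te <- train_rounds[train_rounds$subject_id == s, , drop = FALSE]
        if (method == "lstm") {
          sp <- val_split(tr, seed = seed)
          fit_predict(windows, sp$train, te, target, method, cfg,
                      val_rounds = sp$val)$pred
        } else fit_predict(windows, tr, te, target, method, cfg)$pred
      })
      rec <- do.call(rbind, preds)
      if (stats::sd(rec$y_pred) == 0 || stats::sd(rec$y_true) == 0) -Inf
      else stats::cor(rec$y_true, rec$y_pred)
    }, numeric(1))
    winner <- configs[[which.max(scores)]]
  } else winner <- configs[[1]]
  if (method == "lstm") {
    sp <- val_split(train_rounds, seed = seed)
    fp <- fit_predict(windows, sp$train, test_rounds, target, method, winner,
                      val_rounds = sp$val)
  } else {
    fp <- fit_predict(windows, train_rounds, test_rounds, target, method,
                      winner)
  }
  new_eval_result("held_out", fp$pred, target, method,
                  winner = config_summary(winner))
}
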