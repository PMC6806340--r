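# The tremor_model fitting surface.
#
# Two back-ends estimate a round's tremor subscore from its window features:
#  * boosting — an additive ensemble of regression trees fitted on per-window
#    examples (each window inherits its round's label); a round's estimate is
#    the mean of its window estimates.
#  * lstm — a many-to-one stacked LSTM over the round's window sequence; the
#    final hidden state is mapped through an affine readout to the estimate.
# Estimates are deliberately not clipped to the label range: fractional
# values between the integer clinical scores are meaningful.

#' Gradient-tree-boosting configuration
#'
#' Defaults reflect the study recipe: squared-error objective, learning rate
#' 0.1, and a grid over ensemble size (10-190 by 20), tree depth (3-9 by 2)
#' and the fraction of features sampled per tree (0.1-0.5 by 0.1) — see
#' [default_boosting_grid()].
#'
#' @param n_trees number of regression trees (default 100).
#' @param max_depth maximum tree depth (default 5).
#' @param feature_subsample_fraction fraction of features sampled per tree
#'   (default 0.3).
#' @param learning_rate shrinkage (default 0.1).
#' @param seed integer RNG seed for the tree learner.
#' @return a list of class `boosting_config`.
#' @export
boosting_config <- function(n_trees = 100L, max_depth = 5L,
                            feature_subsample_fraction = 0.3,
                            learning_rate = 0.1, seed = 1L) {
  stopifnot(n_trees >= 1, max_depth >= 1,
            feature_subsample_fraction > 0, feature_subsample_fraction <= 1)
  structure(list(n_trees = as.integer(n_trees),
                 max_depth = as.integer(max_depth),
                 feature_subsample_fraction = feature_subsample_fraction,
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "boosting_config")
}

#' The study's boosting hyperparameter grid
#'
#' @return a data.frame of 200 configurations: `n_trees` in
#'   `seq(10, 190, 20)`, `max_depth` in `c(3, 5, 7, 9)`,
#'   `feature_subsample_fraction` in `seq(0.1, 0.5, 0.1)`.
#' @export
default_boosting_grid <- function() {
  expand.grid(n_trees = seq(10L, 190L, by = 20L),
              max_depth = c(3L, 5L, 7L, 9L),
              feature_subsample_fraction = seq(0.1, 0.5, by = 0.1))
}

#' LSTM configuration
#'
#' Defaults reflect the study recipe: a 3-layer network trained for 200
#' epochs with Adam at learning rate 1e-3, dropout 0.3 after each LSTM
#' layer, mini-batches of 4 rounds (shorter rounds tiled up to the batch's
#' longest), L2 weight penalty, and augmentation by clipping each round at a
#' random start offset each epoch. The hidden-state grid spans 16-224.
#'
#' @param n_layers number of stacked LSTM layers (default 3).
#' @param n_hidden hidden-state dimension (default 32).
#' @param learning_rate Adam step size (default 1e-3).
#' @param epochs training epochs (default 200).
#' @param dropout dropout probability after each LSTM layer (default 0.3).
#' @param batch_size rounds per mini-batch (default 4).
#' @param l2_coefficient L2 penalty on weight matrices (default 1e-4).
#' @param init_sd standard deviation of the normal weight initialization
#'   (default 0.1).
#' @param seed integer RNG seed (initialization, augmentation, dropout).
#' @return a list of class `lstm_config`.
#' @export
lstm_config <- function(n_layers = 3L, n_hidden = 32L, learning_rate = 1e-3,
                        epochs = 200L, dropout = 0.3, batch_size = 4L,
                        l2_coefficient = 1e-4, init_sd = 0.1, seed = 1L) {
  stopifnot(n_layers >= 1, n_hidden >= 1, dropout >= 0, dropout < 1)
  structure(list(n_layers = as.integer(n_layers), n_hidden = as.integer(n_hidden),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 dropout = dropout, batch_size = as.integer(batch_size),
                 l2_coefficient = l2_coefficient, init_sd = init_sd,
                 seed = as.integer(seed)),
            class = "lstm_config")
}

check_windows <- function(windows, features) {
  miss <- setdiff(c("subject_id", "round_index", features), names(windows))
  if (length(miss))
    stop("window table is missing column(s): ", paste(miss, collapse = ", "))
  for (f in features) {
    v <- windows[[f]]
    if (!all(is.finite(v)))
      stop("non-finite values in feature column '", f, "'")
  }
  invisible(TRUE)
}

round_key <- function(df) paste(df$subject_id, df$round_index, sep = "\r")

#' Fit a tremor-severity regression model
#'
#' Fits one of the two back-ends to per-window features labeled at the round
#' level. The sensor scope follows the target: hand targets (`rest_hand`,
#' `action`) use wrist features only, the foot target (`rest_foot`) ankle
#' features only, composite targets (`total`, `rest_hand_foot`) both.
#' Per-feature normalization statistics (mean, sd) are computed from the
#' training windows only, stored with the model, and applied to all later
#' inputs.
#'
#' @param windows data.frame of per-window features with key columns
#'   `subject_id`, `round_index` (see [extract_features()]).
#' @param rounds data.frame with one row per round: `subject_id`,
#'   `round_index`, the seven tremor items and `most_affected_side`
#'   (see [round_table()]).
#' @param target regression target, one of `"total"`, `"rest_hand_foot"`,
#'   `"rest_hand"`, `"rest_foot"`, `"action"`.
#' @param method `"boosting"` or `"lstm"`.
#' @param config a [boosting_config()] or [lstm_config()]; defaults created
#'   when `NULL`.
#' @param normalize standardize features by training mean/sd (default TRUE).
#' @param val_rounds for `method = "lstm"`: optional data.frame (same layout
#'   as `rounds`) naming validation rounds used for best-epoch selection;
#'   their windows must also be present in `windows`.
#' @return an object of class `c("tremor_boost"|"tremor_lstm",
#'   "tremor_model")` with `predict`, `print`, `summary` and (boosting)
#'   [feature_gain()] support.
#' @examples
#' \donttest{
#' coh <- generate_cohort(cohort_spec(n_subjects = 4, round_duration_s = 60),
#'                        seed = 1)
#' windows <- extract_cohort_features(coh$rounds)
#' fit <- tremor_fit(windows, coh$round_table, target = "total",
#'                   config = boosting_config(n_trees = 20))
#' predict(fit, windows)
#' }
#' @export
tremor_fit <- function(windows, rounds, target = c("total", "rest_hand_foot",
                                                   "rest_hand", "rest_foot",
                                                   "action"),
                       method = c("boosting", "lstm"), config = NULL,
                       normalize = TRUE, val_rounds = NULL) {
  target <- match.arg(target)
  method <- match.arg(method)
  scope <- target_scope(target)
  features <- scope_features(scope)
  if (nrow(rounds) == 0L) stop("empty training set")
  check_windows(windows, features)
  y <- target_values(rounds, target)
  rng <- c(total = 28, rest_hand_foot = 8, rest_hand = 4, rest_foot = 4,
           action = 4)[[target]]
  if (any(y < 0 | y > rng)) stop("labels outside the target's range")

  keys <- round_key(rounds)
  wkeys <- round_key(windows)
  train_w <- windows[wkeys %in% keys, , drop = FALSE]
  if (nrow(train_w) == 0L) stop("no windows match the training rounds")
  counts <- table(factor(round_key(train_w), levels = keys))
  if (any(counts == 0L))
    stop("every training round needs at least one window")

  X <- as.matrix(train_w[, features, drop = FALSE])
  if (normalize) {
    center <- colMeans(X)
    scale_ <- apply(X, 2, stats::sd)
    scale_[scale_ == 0] <- 1
  } else {
    center <- rep(0, length(features)); scale_ <- rep(1, length(features))
    names(center) <- names(scale_) <- features
  }
  Xn <- sweep(sweep(X, 2, center), 2, scale_, "/")

  model <- list(method = method, target = target, sensor_scope = scope,
                features = features, center = center, scale = scale_,
                normalize = normalize, registry_hash = registry_hash(),
                n_train_rounds = nrow(rounds), n_train_windows = nrow(train_w))

  if (method == "boosting") {
    if (is.null(config)) config <- boosting_config()
    stopifnot(inherits(config, "boosting_config"))
    ywin <- y[match(round_key(train_w), keys)]
    model$config <- config
    model$fit <- fit_boosting_backend(Xn, ywin, config)
    class(model) <- c("tremor_boost", "tremor_model")
  } else {
    if (is.null(config)) config <- lstm_config()
    stopifnot(inherits(config, "lstm_config"))
    seqs <- split_sequences(Xn, round_key(train_w), keys)
    if (is.null(val_rounds)) {
      vseqs <- seqs; vy <- y
    } else {
      vkeys <- round_key(val_rounds)
      vw <- windows[wkeys %in% vkeys, , drop = FALSE]
      Xv <- sweep(sweep(as.matrix(vw[, features, drop = FALSE]), 2, center),
                  2, scale_, "/")
      vseqs <- split_sequences(Xv, round_key(vw), vkeys)
      vy <- target_values(val_rounds, target)
    }
    model$config <- config
    model$fit <- fit_lstm_backend(seqs, y, vseqs, vy, config)
    class(model) <- c("tremor_lstm", "tremor_model")
  }
  model
}

# Ordered list of per-round feature matrices.
split_sequences <- function(X, wkeys, keys) {
  lapply(keys, function(k) X[wkeys == k, , drop = FALSE])
}

#' Predict round-level tremor subscores
#'
#' Applies the stored normalization and the fitted back-end; for boosting
#' the round estimate is the arithmetic mean of the per-window estimates,
#' for the LSTM a single forward pass over the round's window sequence.
#' Estimates are not clipped to the label range.
#'
#' @param object a fitted `tremor_model`.
#' @param windows per-window feature data.frame (key columns + features).
#' @param ... unused.
#' @return data.frame with `subject_id`, `round_index`, `y_pred`, one row
#'   per round present in `windows`, in order of first appearance.
#' @export
predict.tremor_model <- function(object, windows, ...) {
  check_windows(windows, object$features)
  keys <- unique(round_key(windows))
  wkeys <- round_key(windows)
  counts <- table(factor(wkeys, levels = keys))
  if (any(counts == 0L))
    stop("a round with zero windows cannot be scored; drop it upstream")
  X <- as.matrix(windows[, object$features, drop = FALSE])
  Xn <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  if (object$method == "boosting") {
    yw <- predict_boosting_backend(object$fit, Xn)
    y_pred <- as.numeric(tapply(yw, factor(wkeys, levels = keys), mean))
  } else {
    seqs <- split_sequences(Xn, wkeys, keys)
    y_pred <- predict_lstm_backend(object$fit, seqs)
  }
  first <- match(keys, wkeys)
  data.frame(subject_id = windows$subject_id[first],
             round_index = windows$round_index[first],
             y_pred = y_pred, stringsAsFactors = FALSE)
}

#' @export
print.tremor_model <- function(x, ...) {
  cat(sprintf("<tremor_model> method=%s  target=%s  scope=%s\n",
              x$method, x$target, x$sensor_scope))
  cat(sprintf("  trained on %d rounds (%d windows), %d features%s\n",
              x$n_train_rounds, x$n_train_windows, length(x$features),
              if (x$normalize) ", standardized" else ""))
  invisible(x)
}

#' @export
summary.tremor_model <- function(object, ...) {
  print(object)
  if (object$method == "boosting") {
    g <- feature_gain(object)
    top <- utils::head(g[g$gain_pct > 0.5, ], 10)
    if (nrow(top)) {
      cat("  features with gain > 0.5%:\n")
      for (i in seq_len(nrow(top)))
        cat(sprintf("    %-28s %6.2f%%\n", top$feature[i], top$gain_pct[i]))
    }
  } else {
    cat(sprintf("  best epoch %d (validation r = %.3f)\n",
                object$fit$best_epoch, object$fit$best_val_r))
  }
  invisible(object)
}
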