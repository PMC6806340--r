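# Gradient-tree-boosting back-end (delegates to xgboost: second-order
# additive tree boosting with squared-error loss).

fit_boosting_backend <- function(X, y, config) {
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  params <- list(objective = "reg:squarederror",
                 eta = config$learning_rate,
                 max_depth = config$max_depth,
                 colsample_bytree = config$feature_subsample_fraction,
                 nthread = 1)
  # column subsampling draws from R's RNG; pin it for reproducibility
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)
  xgboost::xgb.train(params = params, data = dtrain,
                     nrounds = config$n_trees, verbose = 0)
}

predict_boosting_backend <- function(fit, X) {
  as.numeric(stats::predict(fit, xgboost::xgb.DMatrix(X, nthread = 1)))
}

#' Per-feature gain shares of a boosting model
#'
#' Total split gain attributed to each feature, normalized to sum to 100%.
#' Features the ensemble never split on have share 0.
#'
#' @param model a fitted boosting `tremor_model`.
#' @return data.frame with `feature` and `gain_pct`, all model features,
#'   sorted by decreasing share.
#' @export
feature_gain <- function(model) {
  if (!inherits(model, "tremor_boost"))
    stop("feature gain is defined for the boosting back-end only")
  imp <- xgboost::xgb.importance(model = model$fit)
  gain <- stats::setNames(rep(0, length(model$features)), model$features)
  if (!is.null(imp) && nrow(imp))
    gain[imp$Feature] <- imp$Gain * 100
  out <- data.frame(feature = names(gain), gain_pct = as.numeric(gain),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$gain_pct, out$feature), ]
  rownames(out) <- NULL
  out
}

#' Features above a gain-share threshold
#'
#' @param model a fitted boosting `tremor_model`.
#' @param threshold minimum gain share in percent (default 0.5).
#' @return the [feature_gain()] rows with `gain_pct > threshold`.
#' @export
important_features <- function(model, threshold = 0.5) {
  g <- feature_gain(model)
  g[g$gain_pct > threshold, , drop = FALSE]
}
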