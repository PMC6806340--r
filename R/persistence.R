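# Model persistence: a directory with JSON metadata plus the back-end's
# native parameter dump. Loading verifies the feature-registry hash so a
# model is never applied to a differently laid-out feature table.

#' Save a fitted tremor model
#'
#' @param model a fitted `tremor_model`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_tremor_model <- function(model, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta <- list(kind = model$method, target = model$target,
               sensor_scope = model$sensor_scope,
               features = model$features,
               center = as.list(model$center), scale = as.list(model$scale),
               normalize = model$normalize,
               registry_hash = model$registry_hash,
               config = unclass(model$config),
               n_train_rounds = model$n_train_rounds,
               n_train_windows = model$n_train_windows)
  if (model$method == "lstm") {
    meta$lstm <- list(params = flatten_lstm(model$fit$params),
                      d_in = nrow(model$fit$params$W_fx),
                      best_epoch = model$fit$best_epoch,
                      best_val_r = model$fit$best_val_r)
  }
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  if (model$method == "boosting")
    xgboost::xgb.save(model$fit, file.path(dir, "boosting.ubj"))
  invisible(dir)
}

#' Load a saved tremor model
#'
#' @param dir directory written by [save_tremor_model()].
#' @return the fitted `tremor_model`.
#' @export
load_tremor_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  if (!identical(meta$registry_hash, registry_hash()))
    stop("model was saved under a different feature registry")
  model <- list(method = meta$kind, target = meta$target,
                sensor_scope = meta$sensor_scope,
                features = meta$features,
                center = unlist(meta$center), scale = unlist(meta$scale),
                normalize = meta$normalize, registry_hash = meta$registry_hash,
                n_train_rounds = meta$n_train_rounds,
                n_train_windows = meta$n_train_windows)
  if (meta$kind == "boosting") {
    model$config <- do.call(boosting_config, meta$config)
    model$fit <- xgboost::xgb.load(file.path(dir, "boosting.ubj"))
    class(model) <- c("tremor_boost", "tremor_model")
  } else {
    model$config <- do.call(lstm_config, meta$config)
    cfg <- model$config
    model$fit <- list(params = unflatten_lstm(meta$lstm$params, meta$lstm$d_in,
                                              cfg$n_hidden, cfg$n_layers),
                      best_epoch = meta$lstm$best_epoch,
                      best_val_r = meta$lstm$best_val_r)
    class(model) <- c("tremor_lstm", "tremor_model")
  }
  model
}
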