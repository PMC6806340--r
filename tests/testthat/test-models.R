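# Regression back-ends: boosting behavior, LSTM equations, aggregation.

make_toy_windows <- function(n_subj = 4, rounds = 2, win = 6, seed = 1) {
  set.seed(seed)
  reg <- feature_registry()
  rows <- list(); tabs <- list()
  for (s in seq_len(n_subj)) {
    rh <- (s - 1) %% 5
    for (r in seq_len(rounds)) {
      X <- matrix(rnorm(win * 78, sd = 0.3), win, 78)
      X[, 2] <- X[, 2] + rh          # wrist_Y_power_4_6 carries the signal
      colnames(X) <- reg
      rows[[length(rows) + 1]] <-
        cbind(data.frame(subject_id = sprintf("T%02d", s), round_index = r,
                         window_index = seq_len(win)), as.data.frame(X))
      tabs[[length(tabs) + 1]] <-
        round_row(sprintf("T%02d", s), r, rest_hand = rh)
    }
  }
  list(windows = do.call(rbind, rows), rounds = do.call(rbind, tabs))
}

test_that("constant labels produce constant zero-error predictions", {
  toy <- make_toy_windows()
  toy$rounds[, grep("rest_|action_", names(toy$rounds))] <- 0L
  fit <- tremor_fit(toy$windows, toy$rounds, target = "total",
                    config = boosting_config(n_trees = 10))
  pred <- predict(fit, toy$windows)
  expect_equal(pred$y_pred, rep(0, nrow(pred)), tolerance = 1e-6)
})

test_that("boosting recovers the leaf means of a perfect threshold split", {
  # one informative feature, two clusters of labels: with enough additive
  # steps the ensemble converges to the per-leaf means
  set.seed(2)
  reg <- feature_registry()
  n <- 80
  X <- matrix(0, n, 78, dimnames = list(NULL, reg))
  X[, 1] <- c(rnorm(n / 2, -2, 0.1), rnorm(n / 2, 2, 0.1))
  y <- rep(c(1, 3), each = n / 2)
  fit <- tremorsense:::fit_boosting_backend(
    X, y, boosting_config(n_trees = 200, max_depth = 1,
                          feature_subsample_fraction = 1, learning_rate = 0.3))
  pred <- tremorsense:::predict_boosting_backend(fit, X)
  expect_equal(mean(pred[1:(n / 2)]), 1, tolerance = 1e-3)
  expect_equal(mean(pred[(n / 2 + 1):n]), 3, tolerance = 1e-3)
})

test_that("training MSE never increases with more trees", {
  toy <- make_toy_windows(seed = 5)
  y <- tremorsense:::target_values(toy$rounds, "rest_hand")
  mses <- vapply(c(5, 20, 60, 120), function(nt) {
    fit <- tremor_fit(toy$windows, toy$rounds, target = "rest_hand",
                      config = boosting_config(n_trees = nt, seed = 3))
    pred <- predict(fit, toy$windows)
    mean((pred$y_pred - y)^2)
  }, numeric(1))
  expect_true(all(diff(mses) <= 1e-8))
})

test_that("round prediction is the mean of window predictions (boosting)", {
  toy <- make_toy_windows(seed = 8)
  fit <- tremor_fit(toy$windows, toy$rounds, target = "rest_hand",
                    config = boosting_config(n_trees = 30))
  pred <- predict(fit, toy$windows)
  # brute-force oracle: per-window back-end predictions averaged by round
  Xn <- sweep(sweep(as.matrix(toy$windows[, fit$features]), 2, fit$center),
              2, fit$scale, "/")
  yw <- tremorsense:::predict_boosting_backend(fit$fit, Xn)
  keys <- paste(toy$windows$subject_id, toy$windows$round_index)
  oracle <- vapply(unique(keys), function(k) sum(yw[keys == k]) /
                     sum(keys == k), numeric(1))
  expect_equal(pred$y_pred, unname(oracle), tolerance = 1e-12)
  # a one-window round predicts exactly its window value
  one <- toy$windows[1, , drop = FALSE]
  expect_equal(predict(fit, one)$y_pred,
               tremorsense:::predict_boosting_backend(fit$fit,
                 Xn[1, , drop = FALSE]),
               tolerance = 1e-12)
})

test_that("boosting is invariant to window order; the LSTM is not", {
  toy <- make_toy_windows(seed = 9)
  fitb <- tremor_fit(toy$windows, toy$rounds, target = "rest_hand",
                     config = boosting_config(n_trees = 30))
  shuf <- toy$windows[rev(seq_len(nrow(toy$windows))), ]
  pb1 <- predict(fitb, toy$windows)
  pb2 <- predict(fitb, shuf)
  pb2 <- pb2[match(paste(pb1$subject_id, pb1$round_index),
                   paste(pb2$subject_id, pb2$round_index)), ]
  expect_equal(pb1$y_pred, pb2$y_pred, tolerance = 1e-12)

  cfg <- lstm_config(n_hidden = 6, epochs = 3, seed = 4)
  fitl <- tremor_fit(toy$windows, toy$rounds, target = "rest_hand",
                     method = "lstm", config = cfg)
  w1 <- toy$windows[toy$windows$subject_id == "T03" &
                      toy$windows$round_index == 1, ]
  w1r <- w1[rev(seq_len(nrow(w1))), ]
  w1r$window_index <- w1$window_index
  expect_false(isTRUE(all.equal(predict(fitl, w1)$y_pred,
                                predict(fitl, w1r)$y_pred,
                                tolerance = 1e-9)))
})

test_that("feature gain is normalized and concentrates on planted signal", {
  toy <- make_toy_windows(n_subj = 5, rounds = 3, win = 10, seed = 10)
  fit <- tremor_fit(toy$windows, toy$rounds, target = "rest_hand",
                    config = boosting_config(n_trees = 60))
  g <- feature_gain(fit)
  expect_equal(sum(g$gain_pct), 100, tolerance = 1e-6)
  expect_identical(g$feature[1], "wrist_Y_power_4_6")
  expect_error(feature_gain(structure(list(), class = c("tremor_lstm",
                                                        "tremor_model"))),
               "boosting")
})

test_that("stored normalization reproduces the training transform", {
  toy <- make_toy_windows(seed = 12)
  fit <- tremor_fit(toy$windows, toy$rounds, target = "rest_hand",
                    config = boosting_config(n_trees = 10))
  X <- as.matrix(toy$windows[, fit$features])
  expect_equal(unname(fit$center), unname(colMeans(X)))
  expect_equal(unname(fit$scale), unname(apply(X, 2, sd)))
})

# ---- LSTM equations ---------------------------------------------------------

test_that("lstm_cell_step matches hand-computed gate arithmetic", {
  zero <- list(Wxi = matrix(0, 1, 1), Whi = matrix(0, 1, 1), bi = 0,
               Wxg = matrix(0, 1, 1), Whg = matrix(0, 1, 1), bg = 0,
               Wxf = matrix(0, 1, 1), Whf = matrix(0, 1, 1), bf = 0,
               Wxo = matrix(0, 1, 1), Who = matrix(0, 1, 1), bo = 0)
  st <- lstm_cell_step(zero, x = 5, h_prev = 2, c_prev = 3)
  # i=f=o=0.5, g=0 => c = 0.5*3, h = 0.5*tanh(1.5)
  expect_equal(st$c, 1.5, tolerance = 1e-12)
  expect_equal(st$h, 0.5 * tanh(1.5), tolerance = 1e-12)

  ones <- lapply(zero, function(v) if (is.matrix(v)) matrix(1, 1, 1) else 0)
  st <- lstm_cell_step(ones, x = 1, h_prev = 0, c_prev = 0)
  sig <- function(z) 1 / (1 + exp(-z))
  c_hand <- sig(1) * tanh(1)
  expect_equal(st$c, c_hand, tolerance = 1e-10)
  expect_equal(st$h, sig(1) * tanh(c_hand), tolerance = 1e-10)
})

test_that("the cell passes memory through when f ~ 1 and i ~ 0", {
  w <- list(Wxi = matrix(0, 1, 1), Whi = matrix(0, 1, 1), bi = -50,
            Wxg = matrix(0, 1, 1), Whg = matrix(0, 1, 1), bg = 0,
            Wxf = matrix(0, 1, 1), Whf = matrix(0, 1, 1), bf = 50,
            Wxo = matrix(0, 1, 1), Who = matrix(0, 1, 1), bo = 0)
  for (alpha in c(-2, 0.5, 3)) {
    st <- lstm_cell_step(w, x = 1, h_prev = 0, c_prev = alpha)
    expect_equal(st$c, alpha, tolerance = 1e-9)
  }
})

test_that("lstm_forward matches an independent scalar oracle", {
  # standalone reimplementation of the recurrence, scalar loops only
  oracle_forward <- function(p, X) {
    H <- ncol(p$W_fx); L <- length(p$layers)
    sig <- function(z) 1 / (1 + exp(-z))
    h <- matrix(0, L, H); cc <- matrix(0, L, H)
    for (t in seq_len(nrow(X))) {
      inp <- numeric(H)
      for (k in seq_len(H))
        inp[k] <- sum(X[t, ] * p$W_fx[, k]) + p$b_fx[k]
      for (l in seq_len(L)) {
        w <- p$layers[[l]]
        i <- g <- f <- o <- numeric(H)
        for (k in seq_len(H)) {
          i[k] <- sig(sum(inp * w$Wxi[, k]) + sum(h[l, ] * w$Whi[, k]) + w$bi[k])
          g[k] <- tanh(sum(inp * w$Wxg[, k]) + sum(h[l, ] * w$Whg[, k]) + w$bg[k])
          f[k] <- sig(sum(inp * w$Wxf[, k]) + sum(h[l, ] * w$Whf[, k]) + w$bf[k])
          o[k] <- sig(sum(inp * w$Wxo[, k]) + sum(h[l, ] * w$Who[, k]) + w$bo[k])
        }
        cc[l, ] <- f * cc[l, ] + i * g
        h[l, ] <- o * tanh(cc[l, ])
        inp <- h[l, ]
      }
    }
    sum(h[L, ] * p$W_hy) + p$b_y
  }
  p <- init_lstm_params(3, lstm_config(n_layers = 2, n_hidden = 2, seed = 21))
  X <- matrix(rnorm(6), 2, 3)
  expect_equal(lstm_forward(p, X), oracle_forward(p, X), tolerance = 1e-10)
  # and the compiled forward agrees with the R reference
  expect_equal(tremorsense:::lstm_forward_cpp(tremorsense:::flatten_lstm(p),
                                              X, 3, 2, 2),
               lstm_forward(p, X), tolerance = 1e-12)
})

test_that("a length-1 sequence reduces to one stacked cell step + readout", {
  cfg <- lstm_config(n_layers = 3, n_hidden = 4, seed = 6)
  p <- init_lstm_params(5, cfg)
  x <- rnorm(5)
  inp <- as.numeric(x %*% p$W_fx) + p$b_fx
  h <- rep(0, 4); cc <- rep(0, 4)
  for (l in 1:3) {
    st <- lstm_cell_step(p$layers[[l]], inp, rep(0, 4), rep(0, 4))
    inp <- st$h
  }
  manual <- as.numeric(inp %*% p$W_hy) + p$b_y
  expect_equal(lstm_forward(p, matrix(x, 1)), manual, tolerance = 1e-12)
})

test_that("LSTM training is reproducible and respects a zero-epoch budget", {
  toy <- make_toy_windows(seed = 14)
  cfg <- lstm_config(n_hidden = 6, epochs = 4, seed = 11)
  f1 <- tremor_fit(toy$windows, toy$rounds, target = "rest_hand",
                   method = "lstm", config = cfg)
  f2 <- tremor_fit(toy$windows, toy$rounds, target = "rest_hand",
                   method = "lstm", config = cfg)
  expect_identical(f1$fit$params, f2$fit$params)
  expect_identical(f1$fit$best_epoch, f2$fit$best_epoch)

  cfg0 <- lstm_config(n_hidden = 6, epochs = 0, seed = 11)
  expect_warning(
    f0 <- tremor_fit(toy$windows, toy$rounds, target = "rest_hand",
                     method = "lstm", config = cfg0), NA)
  p0 <- init_lstm_params(39, cfg0)
  expect_equal(f0$fit$params, p0, tolerance = 1e-12)
  expect_equal(f0$fit$best_epoch, 0L)
})

test_that("lstm_forward is bit-deterministic across calls", {
  p <- init_lstm_params(4, lstm_config(n_hidden = 5, seed = 2))
  X <- matrix(rnorm(40), 10, 4)
  expect_identical(lstm_forward(p, X), lstm_forward(p, X))
})

test_that("models persist and reload with identical predictions", {
  toy <- make_toy_windows(seed = 15)
  dir <- withr::local_tempdir()
  fitb <- tremor_fit(toy$windows, toy$rounds, target = "rest_hand",
                     config = boosting_config(n_trees = 20))
  save_tremor_model(fitb, file.path(dir, "bst"))
  backb <- load_tremor_model(file.path(dir, "bst"))
  expect_equal(predict(backb, toy$windows)$y_pred,
               predict(fitb, toy$windows)$y_pred, tolerance = 1e-9)

  fitl <- tremor_fit(toy$windows, toy$rounds, target = "rest_hand",
                     method = "lstm",
                     config = lstm_config(n_hidden = 5, epochs = 3, seed = 8))
  save_tremor_model(fitl, file.path(dir, "lstm"))
  backl <- load_tremor_model(file.path(dir, "lstm"))
  expect_equal(predict(backl, toy$windows)$y_pred,
               predict(fitl, toy$windows)$y_pred, tolerance = 1e-12)
})

test_that("hand targets use the wrist sensor only", {
  toy <- make_toy_windows(seed = 16)
  fit <- tremor_fit(toy$windows, toy$rounds, target = "rest_hand",
                    config = boosting_config(n_trees = 10))
  expect_length(fit$features, 39L)
  expect_true(all(startsWith(fit$features, "wrist_")))
  fit2 <- tremor_fit(toy$windows, toy$rounds, target = "rest_foot",
                     config = boosting_config(n_trees = 10))
  expect_true(all(startsWith(fit2$features, "ankle_")))
})
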