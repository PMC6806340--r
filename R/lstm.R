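# Many-to-one LSTM round regressor.
#
# Parameter convention (row-vector form): a gate pre-activation is
# x %*% Wx + h %*% Wh + b with Wx, Wh of dimension (input x hidden) and b a
# length-hidden vector. Parameters:
#   W_fx (D x H), b_fx           — linear input transform per window
#   layers[[l]] : Wxi, Whi, bi, Wxg, Whg, bg, Wxf, Whf, bf, Wxo, Who, bo
#   W_hy (H x 1), b_y            — affine readout of the final hidden state
# The R functions here are the reference implementation (used for scoring
# and as the ground truth the compiled training core is tested against);
# training itself runs in C++ (backpropagation through time + Adam).

#' One LSTM cell update
#'
#' Computes the four gates and the state update:
#' `i = sigmoid(x Wxi + h Whi + bi)`, `g = tanh(x Wxg + h Whg + bg)`,
#' `f = sigmoid(x Wxf + h Whf + bf)`, `o = sigmoid(x Wxo + h Who + bo)`,
#' `c = f*c_prev + i*g`, `h = o*tanh(c)`. Pure function of its inputs.
#'
#' @param weights list with elements `Wxi, Whi, bi, Wxg, Whg, bg, Wxf, Whf,
#'   bf, Wxo, Who, bo` (matrices input x hidden, biases length hidden).
#' @param x input vector.
#' @param h_prev,c_prev previous hidden and cell state vectors.
#' @return list with elements `h` and `c`.
#' @export
lstm_cell_step <- function(weights, x, h_prev, c_prev) {
  w <- weights
  x <- rbind(as.numeric(x)); h <- rbind(as.numeric(h_prev))
  if (ncol(x) != nrow(w$Wxi) || ncol(h) != nrow(w$Whi))
    stop("dimension mismatch between inputs and gate weights")
  sig <- function(z) 1 / (1 + exp(-z))
  i <- sig(x %*% w$Wxi + h %*% w$Whi + rbind(w$bi))
  g <- tanh(x %*% w$Wxg + h %*% w$Whg + rbind(w$bg))
  f <- sig(x %*% w$Wxf + h %*% w$Whf + rbind(w$bf))
  o <- sig(x %*% w$Wxo + h %*% w$Who + rbind(w$bo))
  c_new <- f * as.numeric(c_prev) + i * g
  list(h = as.numeric(o * tanh(c_new)), c = as.numeric(c_new))
}

#' Forward pass of the stacked many-to-one LSTM
#'
#' Applies the linear input transform to each window's feature vector, runs
#' the stacked recurrence over all windows in temporal order and maps the
#' final top-layer hidden state through the affine readout. Dropout is a
#' training-time device and is inactive here.
#'
#' @param params parameter list (`W_fx`, `b_fx`, `layers`, `W_hy`, `b_y`);
#'   see [init_lstm_params()].
#' @param X numeric matrix, one row per window (already normalized).
#' @return scalar estimate.
#' @export
lstm_forward <- function(params, X) {
  X <- as.matrix(X)
  if (nrow(X) < 1L) stop("cannot score an empty window sequence")
  H <- ncol(params$W_fx)
  L <- length(params$layers)
  h <- lapply(seq_len(L), function(l) rep(0, H))
  cc <- lapply(seq_len(L), function(l) rep(0, H))
  for (t in seq_len(nrow(X))) {
    inp <- as.numeric(X[t, , drop = FALSE] %*% params$W_fx) + params$b_fx
    for (l in seq_len(L)) {
      st <- lstm_cell_step(params$layers[[l]], inp, h[[l]], cc[[l]])
      h[[l]] <- st$h; cc[[l]] <- st$c
      inp <- st$h
    }
  }
  as.numeric(h[[L]] %*% params$W_hy) + params$b_y
}

#' Initialize LSTM parameters
#'
#' All weights and biases drawn from `Normal(0, init_sd)` under the config
#' seed (reproducible).
#'
#' @param d_in input feature dimension (39 or 78).
#' @param config an [lstm_config()].
#' @return parameter list (`W_fx`, `b_fx`, `layers`, `W_hy`, `b_y`).
#' @export
init_lstm_params <- function(d_in, config) {
  H <- config$n_hidden
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)
  rm_ <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, config$init_sd), nr, nc)
  layers <- lapply(seq_len(config$n_layers), function(l)
    list(Wxi = rm_(H, H), Whi = rm_(H, H), bi = as.numeric(rm_(H, 1)),
         Wxg = rm_(H, H), Whg = rm_(H, H), bg = as.numeric(rm_(H, 1)),
         Wxf = rm_(H, H), Whf = rm_(H, H), bf = as.numeric(rm_(H, 1)),
         Wxo = rm_(H, H), Who = rm_(H, H), bo = as.numeric(rm_(H, 1))))
  list(W_fx = rm_(d_in, H), b_fx = as.numeric(rm_(H, 1)), layers = layers,
       W_hy = rm_(H, 1), b_y = as.numeric(rm_(1, 1)))
}

# Training wrapper around the compiled core. Returns the back-end object
# stored in a tremor_model.
fit_lstm_backend <- function(seqs, y, vseqs, vy, config) {
  if (any(vapply(seqs, nrow, integer(1)) < 1L))
    stop("every training round needs at least one window")
  params0 <- init_lstm_params(ncol(seqs[[1]]), config)
  res <- lstm_train_cpp(flatten_lstm(params0), vapply(seqs, nrow, integer(1)),
                        do.call(rbind, seqs), as.numeric(y),
                        vapply(vseqs, nrow, integer(1)),
                        do.call(rbind, vseqs), as.numeric(vy),
                        ncol(seqs[[1]]), config$n_hidden, config$n_layers,
                        config$epochs, config$learning_rate, config$dropout,
                        config$l2_coefficient, config$batch_size, config$seed)
  if (config$epochs > 0L && !is.finite(res$best_val_r))
    warning("validation correlation undefined for every epoch ",
            "(constant predictions); returning the final-epoch parameters")
  list(params = unflatten_lstm(res$params, ncol(seqs[[1]]), config$n_hidden,
                               config$n_layers),
       best_epoch = res$best_epoch, best_val_r = res$best_val_r,
       val_r_history = res$history)
}

predict_lstm_backend <- function(fit, seqs) {
  vapply(seqs, function(S) lstm_forward_cpp(flatten_lstm(fit$params),
                                            as.matrix(S),
                                            ncol(S), ncol(fit$params$W_fx),
                                            length(fit$params$layers)),
         numeric(1))
}

# Parameter (un)flattening for the compiled core: one numeric vector in a
# fixed order.
flatten_lstm <- function(p) {
  unlist(c(list(as.numeric(p$W_fx), p$b_fx),
           lapply(p$layers, function(l)
             list(as.numeric(l$Wxi), as.numeric(l$Whi), l$bi,
                  as.numeric(l$Wxg), as.numeric(l$Whg), l$bg,
                  as.numeric(l$Wxf), as.numeric(l$Whf), l$bf,
                  as.numeric(l$Wxo), as.numeric(l$Who), l$bo)),
           list(as.numeric(p$W_hy), p$b_y)), use.names = FALSE)
}

unflatten_lstm <- function(v, d_in, H, L) {
  pos <- 0L
  take <- function(n) {
    out <- v[(pos + 1L):(pos + n)]
    pos <<- pos + n
    out
  }
  W_fx <- matrix(take(d_in * H), d_in, H)
  b_fx <- take(H)
  layers <- lapply(seq_len(L), function(l) {
    l <- list()
    for (nm in c("Wxi", "Whi", "bi", "Wxg", "Whg", "bg",
                 "Wxf", "Whf", "bf", "Wxo", "Who", "bo")) {
      l[[nm]] <- if (startsWith(nm, "b")) take(H) else matrix(take(H * H), H, H)
    }
    l
  })
  W_hy <- matrix(take(H), H, 1)
  b_y <- take(1)
  stopifnot(pos == length(v))
  list(W_fx = W_fx, b_fx = b_fx, layers = layers, W_hy = W_hy, b_y = b_y)
}
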