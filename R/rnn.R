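#' Recurrent engagement-predictor parameters
#'
#' A minimal single-layer recurrent network: hidden state
#' `h(t) = tanh(W_h x(t) + U_h h(t-1) + b_h)` and engagement prediction
#' `E(t+1) = sigma(W_e h(t) + b_e)`. Written from scratch (plain matrices,
#' full backpropagation through time) so gradients are checkable against
#' finite differences.
#'
#' @param input_dim,hidden_dim layer sizes.
#' @param seed seed for the Gaussian initialization.
#' @param init_sd standard deviation of the initial weights.
#' @return an `rnn_params` list with `w_h`, `u_h`, `b_h`, `w_e`, `b_e`.
#' @export
rnn_params <- function(input_dim, hidden_dim, seed = 1L, init_sd = 0.3) {
  with_seed(seed, {
    structure(list(
      w_h = matrix(rnorm(hidden_dim * input_dim, 0, init_sd), hidden_dim),
      u_h = matrix(rnorm(hidden_dim * hidden_dim, 0, init_sd), hidden_dim),
      b_h = rnorm(hidden_dim, 0, init_sd),
      w_e = matrix(rnorm(hidden_dim, 0, init_sd), 1L),
      b_e = rnorm(1, 0, init_sd)
    ), class = "rnn_params")
  })
}

#' Build recurrent parameters from explicit matrices
#'
#' @param w_h input-to-hidden matrix (`hidden x input`).
#' @param u_h hidden-to-hidden matrix (`hidden x hidden`).
#' @param b_h hidden bias vector.
#' @param w_e output weight row (`1 x hidden`).
#' @param b_e output bias scalar.
#' @return an `rnn_params` list.
#' @export
rnn_params_from <- function(w_h, u_h, b_h, w_e, b_e) {
  w_h <- as.matrix(w_h); u_h <- as.matrix(u_h); w_e <- matrix(w_e, nrow = 1L)
  h <- nrow(w_h)
  if (nrow(u_h) != h || ncol(u_h) != h || length(b_h) != h ||
      ncol(w_e) != h || length(b_e) != 1L) {
    abort("parameter shapes are mutually inconsistent.",
          class = "apeo_shape_error")
  }
  structure(list(w_h = w_h, u_h = u_h, b_h = b_h, w_e = w_e, b_e = b_e),
            class = "rnn_params")
}

#' Forward pass of the engagement predictor
#'
#' @param x input matrix, one row per time step.
#' @param params an `rnn_params` object.
#' @param h0 initial hidden state (default zeros).
#' @return list with `pred` (predicted engagement per step, strictly in
#'   (0, 1)) and `hidden` (hidden states, one row per step).
#' @export
rnn_forward <- function(x, params, h0 = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 1) {
    abort("`x` must contain at least one time step.",
          class = "apeo_invalid_argument")
  }
  if (ncol(x) != ncol(params$w_h)) {
    abort(sprintf("`x` has %d columns but the network expects %d inputs.",
                  ncol(x), ncol(params$w_h)),
          class = "apeo_shape_error")
  }
  hdim <- nrow(params$w_h)
  h <- if (is.null(h0)) numeric(hdim) else h0
  n <- nrow(x)
  hs <- matrix(0, n, hdim)
  pred <- numeric(n)
  for (t in seq_len(n)) {
    h <- tanh(drop(params$w_h %*% x[t, ]) + drop(params$u_h %*% h) + params$b_h)
    hs[t, ] <- h
    pred[t] <- sigmoid(drop(params$w_e %*% h) + params$b_e)
  }
  list(pred = pred, hidden = hs)
}

# Batched forward+backward over sequences of identical length.
# xarr: array (time, input_dim, n_seq); targets: matrix (time, n_seq).
# Returns loss and parameter gradients of sum_i sum_t (e - p)^2.
rnn_bptt <- function(xarr, targets, params) {
  tl <- dim(xarr)[1]; d <- dim(xarr)[2]; n <- dim(xarr)[3]
  hdim <- nrow(params$w_h)
  hs <- array(0, c(tl, hdim, n))
  ps <- matrix(0, tl, n)
  h <- matrix(0, hdim, n)
  for (t in seq_len(tl)) {
    xt <- matrix(xarr[t, , ], nrow = d)
    h <- tanh(params$w_h %*% xt + params$u_h %*% h +
                matrix(params$b_h, hdim, n))
    hs[t, , ] <- h
    ps[t, ] <- sigmoid(drop(params$w_e %*% h) + params$b_e)
  }
  loss <- sum((targets - ps)^2)
  g <- list(w_h = 0 * params$w_h, u_h = 0 * params$u_h,
            b_h = 0 * params$b_h, w_e = 0 * params$w_e, b_e = 0)
  da_next <- matrix(0, hdim, n)
  for (t in rev(seq_len(tl))) {
    ht <- matrix(hs[t, , ], nrow = hdim)
    dz <- 2 * (ps[t, ] - targets[t, ]) * ps[t, ] * (1 - ps[t, ])  # 1 x n
    g$w_e <- g$w_e + matrix(dz, 1L) %*% t(ht)
    g$b_e <- g$b_e + sum(dz)
    dh <- t(params$w_e) %*% matrix(dz, 1L) + t(params$u_h) %*% da_next
    da <- dh * (1 - ht^2)
    xt <- matrix(xarr[t, , ], nrow = d)
    g$w_h <- g$w_h + da %*% t(xt)
    hprev <- if (t > 1) matrix(hs[t - 1, , ], nrow = hdim)
             else matrix(0, hdim, n)
    g$u_h <- g$u_h + da %*% t(hprev)
    g$b_h <- g$b_h + rowSums(da)
    da_next <- da
  }
  list(loss = loss, grads = g)
}

as_rnn_batch <- function(dataset) {
  lens <- vapply(dataset, function(s) nrow(as.matrix(s$x)), integer(1))
  if (length(unique(lens)) != 1L) {
    abort("all sequences must share one length for batched training.",
          class = "apeo_shape_error")
  }
  tl <- lens[1]
  d <- ncol(as.matrix(dataset[[1]]$x))
  n <- length(dataset)
  xarr <- array(0, c(tl, d, n))
  targets <- matrix(0, tl, n)
  for (i in seq_len(n)) {
    xarr[, , i] <- as.matrix(dataset[[i]]$x)
    targets[, i] <- dataset[[i]]$e
  }
  list(x = xarr, e = targets)
}

#' Train the engagement predictor by full-batch gradient descent
#'
#' Minimizes the summed squared prediction error over all sequences and
#' steps, with full backpropagation through time and plain gradient descent
#' (no adaptive optimizer, so runs are trivially deterministic for a fixed
#' initialization seed).
#'
#' @param dataset list of sequences, each `list(x = matrix, e = vector)`
#'   with targets in (0, 1); all sequences must share one length.
#' @param params initial `rnn_params`, or `NULL` to initialize from `seed`.
#' @param hidden_dim hidden size used when `params` is `NULL`.
#' @param lr learning rate (> 0).
#' @param epochs number of full-batch epochs.
#' @param seed initialization seed.
#' @return an `apeo_rnn_fit` with `params`, `loss_trace` tibble
#'   (`epoch`, `loss`), `n_seq`; supports [tidy()], [glance()] and
#'   [autoplot()].
#' @export
rnn_train <- function(dataset, params = NULL, hidden_dim = 4L, lr = 0.01,
                      epochs = 200L, seed = 1L) {
  if (length(dataset) < 1) {
    abort("`dataset` must contain at least one sequence.",
          class = "apeo_invalid_argument")
  }
  if (lr <= 0) {
    abort("`lr` must be > 0.", class = "apeo_invalid_argument")
  }
  batch <- as_rnn_batch(dataset)
  if (is.null(params)) {
    params <- rnn_params(dim(batch$x)[2], hidden_dim, seed = seed)
  }
  trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    bp <- rnn_bptt(batch$x, batch$e, params)
    trace[ep] <- bp$loss
    params$w_h <- params$w_h - lr * bp$grads$w_h
    params$u_h <- params$u_h - lr * bp$grads$u_h
    params$b_h <- params$b_h - lr * bp$grads$b_h
    params$w_e <- params$w_e - lr * bp$grads$w_e
    params$b_e <- params$b_e - lr * bp$grads$b_e
  }
  structure(list(params = params,
                 loss_trace = tibble(epoch = seq_len(epochs), loss = trace),
                 n_seq = length(dataset)),
            class = "apeo_rnn_fit")
}

#' Mean squared prediction error of a fitted predictor on a dataset
#'
#' @param fit an `apeo_rnn_fit` (or bare `rnn_params`).
#' @param dataset sequences as in [rnn_train()].
#' @return mean squared error per prediction.
#' @export
rnn_mse <- function(fit, dataset) {
  params <- if (inherits(fit, "apeo_rnn_fit")) fit$params else fit
  errs <- vapply(dataset, function(s) {
    p <- rnn_forward(s$x, params)$pred
    mean((s$e - p)^2)
  }, numeric(1))
  mean(errs)
}

#' Serialize / restore recurrent parameters as JSON
#'
#' @param params an `rnn_params`.
#' @param path JSON file path.
#' @return `write_rnn_params` returns `path` invisibly; `read_rnn_params`
#'   the restored `rnn_params`.
#' @export
write_rnn_params <- function(params, path) {
  jsonlite::write_json(
    list(w_h = params$w_h, u_h = params$u_h, b_h = params$b_h,
         w_e = params$w_e, b_e = params$b_e),
    path, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_rnn_params
#' @export
read_rnn_params <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  rnn_params_from(raw$w_h, raw$u_h, raw$b_h, raw$w_e, raw$b_e)
}
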