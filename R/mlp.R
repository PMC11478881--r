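## Minimal feed-forward network: dense ReLU layers, linear output, Adam on
## minibatch mean-squared error. Pure matrix arithmetic, deterministic under
## the session RNG, which train_clock() seeds.

mlp_init <- function(widths) {
  ## widths = c(p, hidden..., 1); He-scaled Gaussian init
  L <- length(widths) - 1
  lapply(seq_len(L), function(l) {
    p_in <- widths[l]; p_out <- widths[l + 1]
    list(W = matrix(stats::rnorm(p_in * p_out, 0, sqrt(2 / p_in)), p_in, p_out),
         b = matrix(0, 1, p_out))
  })
}

mlp_forward <- function(params, X) {
  L <- length(params)
  act <- vector("list", L + 1)
  act[[1]] <- X
  for (l in seq_len(L)) {
    z <- act[[l]] %*% params[[l]]$W +
      matrix(params[[l]]$b, nrow(act[[l]]), ncol(params[[l]]$b), byrow = TRUE)
    act[[l + 1]] <- if (l < L) pmax(z, 0) else z
  }
  act
}

mlp_predict <- function(params, X) {
  drop(mlp_forward(params, X)[[length(params) + 1]])
}

## gradients of mean((yhat - y)^2) wrt all weights
mlp_gradients <- function(params, act, y) {
  L <- length(params)
  m <- length(y)
  grads <- vector("list", L)
  delta <- 2 * (act[[L + 1]] - matrix(y)) / m
  for (l in L:1) {
    grads[[l]] <- list(W = crossprod(act[[l]], delta),
                       b = colSums(delta))
    if (l > 1) {
      delta <- (delta %*% t(params[[l]]$W)) * (act[[l]] > 0)
    }
  }
  grads
}

mlp_train <- function(X, y, hidden, epochs, batch_size, learning_rate,
                      X_valid = NULL, y_valid = NULL, patience = NULL) {
  widths <- c(ncol(X), hidden, 1L)
  params <- mlp_init(widths)
  L <- length(params)
  mom <- lapply(params, function(p) list(W = p$W * 0, b = p$b * 0))
  vel <- lapply(params, function(p) list(W = p$W * 0, b = p$b * 0))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  t_step <- 0
  n <- nrow(X)
  epoch_loss <- numeric(epochs)
  valid_loss <- rep(NA_real_, epochs)
  best <- list(loss = Inf, params = params, epoch = 0L)
  for (e in seq_len(epochs)) {
    idx <- sample.int(n)
    for (start in seq(1, n, by = batch_size)) {
      rows <- idx[start:min(start + batch_size - 1, n)]
      act <- mlp_forward(params, X[rows, , drop = FALSE])
      grads <- mlp_gradients(params, act, y[rows])
      t_step <- t_step + 1
      corr1 <- 1 - b1^t_step
      corr2 <- 1 - b2^t_step
      for (l in seq_len(L)) {
        for (nm in c("W", "b")) {
          g <- grads[[l]][[nm]]
          mom[[l]][[nm]] <- b1 * mom[[l]][[nm]] + (1 - b1) * g
          vel[[l]][[nm]] <- b2 * vel[[l]][[nm]] + (1 - b2) * g^2
          step <- learning_rate * (mom[[l]][[nm]] / corr1) /
            (sqrt(vel[[l]][[nm]] / corr2) + eps)
          params[[l]][[nm]] <- params[[l]][[nm]] - step
        }
      }
    }
    epoch_loss[e] <- mean((mlp_predict(params, X) - y)^2)
    if (!is.null(X_valid)) {
      valid_loss[e] <- mean((mlp_predict(params, X_valid) - y_valid)^2)
      if (valid_loss[e] < best$loss)
        best <- list(loss = valid_loss[e], params = params, epoch = e)
      if (!is.null(patience) && e - best$epoch >= patience) {
        epoch_loss <- epoch_loss[seq_len(e)]
        valid_loss <- valid_loss[seq_len(e)]
        params <- best$params
        break
      }
    }
  }
  list(params = params, training_loss = epoch_loss, validation_loss = valid_loss)
}
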