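#' Multilayer perceptron regression with ADAM
#'
#' A small fully connected network (tanh hidden layers, linear output)
#' trained by full-batch ADAM on the mean-squared error, with inputs and
#' outputs standardized internally. This is the package's network backend for
#' realizing smooth invertible maps (e.g. data-driven coordinates to
#' candidate effective parameters and back); the loss is reported in the
#' original output units.
#'
#' @param x matrix / data frame of inputs (rows = samples).
#' @param y matrix / data frame / vector of outputs.
#' @param hidden integer vector of hidden-layer widths (default `rep(30, 5)`:
#'   five hidden layers of 30 tanh units).
#' @param epochs number of ADAM steps (full batch; default 20000).
#' @param lr ADAM learning rate (default 1e-3).
#' @param seed seed for weight initialization.
#' @param patience stop early when the training MSE has not improved by
#'   `tol_rel` over this many epochs (default 2000).
#' @param tol_rel relative improvement tolerance for early stopping.
#' @param verbose print progress every 2000 epochs.
#' @return Object of class `effparam_mlp` with the weights, scalers, and the
#'   final `mse` (original units).
#' @export
mlp_fit <- function(x, y, hidden = rep(30L, 5L), epochs = 20000, lr = 1e-3,
                    seed = 1, patience = 2000, tol_rel = 1e-4,
                    verbose = FALSE) {
  x <- as_matrix(x); y <- as_matrix(y)
  stopifnot(nrow(x) == nrow(y))
  scx <- col_scaler(x); scy <- col_scaler(y)
  X <- scale_apply(x, scx); Y <- scale_apply(y, scy)
  sizes <- c(ncol(X), hidden, ncol(Y))
  L <- length(sizes) - 1L
  with_seed(seed, {
    W <- lapply(seq_len(L), function(l) {
      matrix(rnorm(sizes[l] * sizes[l + 1], sd = sqrt(1 / sizes[l])),
             sizes[l], sizes[l + 1])
    })
    b <- lapply(seq_len(L), function(l) numeric(sizes[l + 1]))
  })
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(x_) x_ * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; epsadam <- 1e-8
  n <- nrow(X)
  best <- Inf; best_epoch <- 0L
  for (it in seq_len(epochs)) {
    # forward
    a <- vector("list", L + 1L); a[[1]] <- X
    for (l in seq_len(L)) {
      z <- a[[l]] %*% W[[l]]
      z <- sweep(z, 2, b[[l]], "+")
      a[[l + 1]] <- if (l < L) tanh(z) else z
    }
    err <- a[[L + 1]] - Y
    mse <- mean(err^2)
    if (mse < best * (1 - tol_rel)) { best <- mse; best_epoch <- it }
    if (it - best_epoch > patience) break
    # backward
    G <- 2 * err / length(err)
    for (l in L:1) {
      gW <- crossprod(a[[l]], G)
      gb <- colSums(G)
      if (l > 1) {
        G <- (G %*% t(W[[l]])) * (1 - a[[l]]^2)
      }
      mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
      vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
      mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
      vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
      corr1 <- 1 - beta1^it; corr2 <- 1 - beta2^it
      W[[l]] <- W[[l]] - lr * (mW[[l]] / corr1) / (sqrt(vW[[l]] / corr2) + epsadam)
      b[[l]] <- b[[l]] - lr * (mb[[l]] / corr1) / (sqrt(vb[[l]] / corr2) + epsadam)
    }
    if (verbose && it %% 2000 == 0) {
      message(sprintf("epoch %d: standardized mse %.3e", it, mse))
    }
  }
  model <- structure(
    list(W = W, b = b, scx = scx, scy = scy, hidden = hidden, seed = seed,
         epochs_run = it, out_names = colnames(y)),
    class = "effparam_mlp")
  pred <- predict(model, x)
  model$mse <- mean((pred - y)^2)
  model
}

#' @export
predict.effparam_mlp <- function(object, newdata, ...) {
  A <- scale_apply(newdata, object$scx)
  L <- length(object$W)
  for (l in seq_len(L)) {
    A <- sweep(A %*% object$W[[l]], 2, object$b[[l]], "+")
    if (l < L) A <- tanh(A)
  }
  out <- scale_invert(A, object$scy)
  colnames(out) <- object$out_names
  out
}

#' @export
print.effparam_mlp <- function(x, ...) {
  cat(sprintf("<effparam_mlp> %s; trained %d epochs, mse = %.3e\n",
              paste(c(length(x$scx$mu), x$hidden, length(x$scy$mu)),
                    collapse = "-"),
              x$epochs_run, x$mse))
  invisible(x)
}
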