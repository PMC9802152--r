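# Minimal reverse-mode automatic differentiation over matrices.
#
# The conformal autoencoder penalizes inner products of *input*-gradients of
# its latent coordinates, so its training gradient needs derivatives of
# expressions that themselves contain first derivatives (double backprop).
# No installed package provides this, so the training loss is built on a
# small tape: each op records its parents and a pullback, and `tp_backward()`
# accumulates gradients in reverse creation order. Only the ops needed by
# the package's networks are implemented.

tape_new <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- list()
  t$k <- 0L
  t
}

tp_node <- function(tape, value, parents = list(), backfn = NULL,
                    param = FALSE) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backfn <- backfn
  nd$param <- param
  tape$k <- tape$k + 1L
  tape$nodes[[tape$k]] <- nd
  nd
}

tp_const <- function(tape, x) tp_node(tape, x)
tp_param <- function(tape, x) tp_node(tape, x, param = TRUE)

tp_acc <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
}

tp_matmul <- function(a, b, tape, tb = FALSE) {
  v <- if (tb) a$value %*% t(b$value) else a$value %*% b$value
  tp_node(tape, v, list(a, b), function(G, nd) {
    if (tb) {
      tp_acc(a, G %*% b$value)
      tp_acc(b, crossprod(G, a$value))
    } else {
      tp_acc(a, tcrossprod(G, b$value))
      tp_acc(b, crossprod(a$value, G))
    }
  })
}

tp_add_bias <- function(a, bias, tape) {
  tp_node(tape, sweep(a$value, 2, bias$value, "+"), list(a, bias),
          function(G, nd) {
            tp_acc(a, G)
            tp_acc(bias, colSums(G))
          })
}

tp_add <- function(a, b, tape) {
  tp_node(tape, a$value + b$value, list(a, b), function(G, nd) {
    tp_acc(a, G); tp_acc(b, G)
  })
}

tp_sub <- function(a, b, tape) {
  tp_node(tape, a$value - b$value, list(a, b), function(G, nd) {
    tp_acc(a, G); tp_acc(b, -G)
  })
}

tp_mul <- function(a, b, tape) {
  tp_node(tape, a$value * b$value, list(a, b), function(G, nd) {
    tp_acc(a, G * b$value); tp_acc(b, G * a$value)
  })
}

tp_tanh <- function(a, tape) {
  v <- tanh(a$value)
  tp_node(tape, v, list(a), function(G, nd) tp_acc(a, G * (1 - nd$value^2)))
}

# 1 - tanh(z)^2 expressed in terms of the activation a = tanh(z)
tp_one_minus_sq <- function(a, tape) {
  tp_node(tape, 1 - a$value^2, list(a), function(G, nd) {
    tp_acc(a, -2 * a$value * G)
  })
}

tp_square <- function(a, tape) {
  tp_node(tape, a$value^2, list(a), function(G, nd) tp_acc(a, 2 * a$value * G))
}

tp_rowsum <- function(a, tape) {
  tp_node(tape, matrix(rowSums(a$value), ncol = 1), list(a), function(G, nd) {
    tp_acc(a, matrix(G, nrow(a$value), ncol(a$value)))
  })
}

tp_mean_all <- function(a, tape) {
  tp_node(tape, matrix(mean(a$value), 1, 1), list(a), function(G, nd) {
    tp_acc(a, matrix(G[1] / length(a$value), nrow(a$value), ncol(a$value)))
  })
}

tp_scale <- function(a, s, tape) {
  tp_node(tape, a$value * s, list(a), function(G, nd) tp_acc(a, G * s))
}

tp_cols <- function(a, idx, tape) {
  tp_node(tape, a$value[, idx, drop = FALSE], list(a), function(G, nd) {
    Z <- matrix(0, nrow(a$value), ncol(a$value))
    Z[, idx] <- G
    tp_acc(a, Z)
  })
}

# Row-broadcast of column i of a parameter matrix: each of the n rows equals
# W[, i]. Seeds the reverse sweep that forms input-gradients of latent i.
tp_row_broadcast <- function(w, i, n, tape) {
  tp_node(tape, matrix(w$value[, i], n, nrow(w$value), byrow = TRUE), list(w),
          function(G, nd) {
            Z <- matrix(0, nrow(w$value), ncol(w$value))
            Z[, i] <- colSums(G)
            tp_acc(w, Z)
          })
}

tp_backward <- function(tape, loss) {
  loss$grad <- matrix(1, 1, 1)
  for (k in tape$k:1) {
    nd <- tape$nodes[[k]]
    if (!is.null(nd$grad) && !is.null(nd$backfn)) nd$backfn(nd$grad, nd)
  }
  invisible(NULL)
}
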