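# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

as_matrix <- function(x) {
  if (is.matrix(x)) x else as.matrix(as.data.frame(x))
}

# Squared Euclidean distance matrix between rows of A (and rows of B).
sq_dist <- function(A, B = NULL) {
  A <- as_matrix(A)
  a2 <- rowSums(A^2)
  if (is.null(B)) {
    D2 <- -2 * tcrossprod(A)
    D2 <- D2 + outer(a2, a2, "+")
  } else {
    B <- as_matrix(B)
    D2 <- -2 * tcrossprod(A, B)
    D2 <- D2 + outer(a2, rowSums(B^2), "+")
  }
  D2[D2 < 0] <- 0
  D2
}

# Column-standardization bundle used by the neural-network code.
col_scaler <- function(X) {
  X <- as_matrix(X)
  mu <- colMeans(X)
  sg <- apply(X, 2, sd)
  sg[sg < .Machine$double.eps] <- 1
  list(mu = mu, sd = sg)
}

scale_apply <- function(X, sc) sweep(sweep(as_matrix(X), 2, sc$mu), 2, sc$sd, "/")
scale_invert <- function(Z, sc) sweep(sweep(as_matrix(Z), 2, sc$sd, "*"), 2, sc$mu, "+")
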