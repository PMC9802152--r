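#' Jointly smooth functions over two row-aligned datasets
#'
#' Extracts functions that are simultaneously smooth over two views of the
#' same samples -- here, functions of the original parameters and functions
#' of the output measurements. For each view a Gaussian-kernel eigenbasis is
#' computed (kernel scale = median squared pairwise distance on standardized
#' columns); the singular value decomposition of the column-concatenation
#' `[U1 U2]` of the two orthonormal bases yields left singular vectors (the
#' JSFs) with singular values in `[0, sqrt(2)]`. A score near `sqrt(2)` means
#' the function lies in both smooth function spaces at once: it is a common,
#' jointly smooth variable -- an effective parameter. Scores near 1 indicate
#' a function smooth over one view only.
#'
#' @param X1 first view (e.g. time-delayed output measurements), matrix-like.
#' @param X2 second view (e.g. parameter vectors), same row count.
#' @param d1,d2 number of kernel eigenfunctions per view (default 32; larger
#'   bases resolve near-degenerate output directions and high harmonics,
#'   which blurs the leading joint function).
#' @param M number of jointly smooth functions to return (default 25).
#' @param standardize length-2 logical: z-score the columns of `X1` / `X2`
#'   before building kernels. The default `c(FALSE, TRUE)` leaves output
#'   measurements on their common concentration scale (standardizing
#'   near-saturated columns amplifies numerically tiny directions) while
#'   putting heterogeneous parameter units on a comparable scale.
#' @return Object of class `jsf_basis`: JSF values (`n x M`, orthonormal
#'   columns), `scores` (nonincreasing), and the per-view eigenbases.
#' @export
jsf_extract <- function(X1, X2, d1 = 32, d2 = 32, M = 25,
                        standardize = c(FALSE, TRUE)) {
  X1 <- as_matrix(X1); X2 <- as_matrix(X2)
  if (nrow(X1) != nrow(X2)) abort("X1 and X2 must have the same number of rows")
  n <- nrow(X1)
  d1 <- min(d1, n - 2L); d2 <- min(d2, n - 2L)
  if (M > d1 + d2) abort("M cannot exceed d1 + d2")
  standardize <- rep_len(standardize, 2L)
  basis <- function(X, d, std) {
    if (std) X <- scale(X)
    X[is.nan(X)] <- 0
    D2 <- sq_dist(X)
    eps <- median(D2[upper.tri(D2)])
    K <- exp(-D2 / eps)
    eig <- eigen(K, symmetric = TRUE)
    # the leading eigenvector is (near-)constant: trivially smooth over any
    # dataset, so it is dropped before the joint decomposition
    keep <- seq_len(d) + 1L
    list(U = fix_signs(eig$vectors[, keep, drop = FALSE]),
         values = eig$values[keep], epsilon = eps)
  }
  b1 <- basis(X1, d1, standardize[1])
  b2 <- basis(X2, d2, standardize[2])
  sv <- svd(cbind(b1$U, b2$U), nu = M, nv = 0)
  F_ <- sv$u
  scores <- sv$d[seq_len(M)]
  # Scores close to sqrt(2) are numerically degenerate (every smooth function
  # of a common variable is jointly smooth), so the SVD rotation within that
  # block is arbitrary. Rotate the block to descending smoothness under the
  # combined kernel quadratic form, making the first JSF the smoothest joint
  # function (typically monotone in the underlying effective parameter).
  blk <- which(scores >= 0.9 * sqrt(2))
  if (length(blk) > 1) {
    Fb <- F_[, blk, drop = FALSE]
    A1 <- crossprod(b1$U, Fb) * sqrt(pmax(b1$values, 0))
    A2 <- crossprod(b2$U, Fb) * sqrt(pmax(b2$values, 0))
    S <- crossprod(A1) + crossprod(A2)
    rot <- eigen((S + t(S)) / 2, symmetric = TRUE)
    F_[, blk] <- Fb %*% rot$vectors
  }
  F_ <- fix_signs(F_)
  colnames(F_) <- paste0("jsf", seq_len(M))
  structure(
    list(functions = F_, scores = scores, basis1 = b1, basis2 = b2,
         n = n, d1 = d1, d2 = d2, ambient2 = ncol(X2)),
    class = "jsf_basis")
}

#' @export
print.jsf_basis <- function(x, ...) {
  cat(sprintf("<jsf_basis> n = %d, %d functions; leading scores: %s (max sqrt(2) = %.3f)\n",
              x$n, ncol(x$functions),
              paste(signif(head(x$scores, 5), 3), collapse = ", "), sqrt(2)))
  invisible(x)
}

#' Count jointly smooth functions by the score gap
#'
#' Retains the scores within `threshold` of the theoretical maximum
#' `sqrt(2)` (default `0.9 * sqrt(2)`). If every score qualifies a warning is
#' raised, since the gap is then uninformative.
#'
#' @param scores nonincreasing score vector from [jsf_extract()].
#' @param threshold absolute retention cutoff (default `0.9 * sqrt(2)`).
#' @return Integer count of retained functions.
#' @export
jsf_score_gap <- function(scores, threshold = 0.9 * sqrt(2)) {
  keep <- sum(scores >= threshold)
  if (keep == length(scores)) {
    warn("all scores lie near sqrt(2); no gap detected, every function retained")
  }
  keep
}

#' Redundant parameter combinations from a JSF basis
#'
#' The jointly smooth functions span the parameter combinations that the
#' output can see. Their complement within the smooth function space over
#' the parameter view -- the parameter-kernel eigenfunctions projected
#' orthogonally to the span of the retained JSFs (and orthonormalized) --
#' varies over the parameter data while remaining invisible to the output:
#' these are the redundant parameter combinations, and their level curves on
#' a level set of the retained JSFs trace parameter changes with unchanged
#' behavior.
#'
#' @param basis a [jsf_extract()] result.
#' @param n_eff number of effective parameters (the intrinsic dimension of
#'   the model manifold, known in advance from [intrinsic_dimension()];
#'   defaults to the [jsf_independent_count()] estimate, which can be fooled
#'   by highly oscillatory harmonics -- prefer passing the known value).
#' @param n_retained number of leading JSFs treated as effective (default:
#'   [jsf_score_gap()] on the basis scores).
#' @param n_redundant number of redundant functions to return (default:
#'   parameter-view ambient dimension minus `n_eff`).
#' @return Matrix `n x n_redundant` of redundant-function values, columns
#'   orthonormal and orthogonal to every retained JSF.
#' @export
jsf_redundant_combinations <- function(basis, n_eff = NULL, n_retained = NULL,
                                       n_redundant = NULL) {
  stopifnot(inherits(basis, "jsf_basis"))
  if (is.null(n_retained)) {
    n_retained <- suppressWarnings(jsf_score_gap(basis$scores))
  }
  U2 <- basis$basis2$U
  if (is.null(n_redundant)) {
    if (is.null(n_eff)) n_eff <- jsf_independent_count(basis)
    n_redundant <- max(0L, basis$ambient2 - n_eff)
  }
  if (n_redundant == 0L || n_retained >= ncol(U2) + 1L) {
    return(matrix(numeric(0), basis$n, 0))
  }
  F_ <- basis$functions[, seq_len(max(n_retained, 1L)), drop = FALSE]
  # weight the parameter eigenfunctions by their kernel eigenvalues so the
  # projected complement is ordered by smoothness over the parameter view
  Uw <- sweep(U2, 2, pmax(basis$basis2$values, 0), "*")
  V <- Uw - F_ %*% crossprod(F_, Uw)
  sv <- svd(V, nu = min(n_redundant, ncol(V)), nv = 0)
  R <- fix_signs(sv$u[, seq_len(n_redundant), drop = FALSE])
  colnames(R) <- paste0("redundant", seq_len(ncol(R)))
  R
}

#' Number of functionally independent jointly smooth functions
#'
#' Harmonics of an effective parameter are themselves jointly smooth, so the
#' count of scores near `sqrt(2)` overstates the number of effective
#' parameters. This applies the parsimonious local-linear-regression test to
#' the retained JSF columns and counts the functionally independent ones --
#' the number of effective parameters the two views share.
#'
#' @param basis a [jsf_extract()] result.
#' @param threshold residual retention threshold (default 0.5).
#' @param max_points subsample cap for the local regressions.
#' @return Integer count.
#' @export
jsf_independent_count <- function(basis, threshold = 0.5, max_points = 1000) {
  stopifnot(inherits(basis, "jsf_basis"))
  n_ret <- suppressWarnings(jsf_score_gap(basis$scores))
  if (n_ret <= 1) return(n_ret)
  F_ <- basis$functions[, seq_len(n_ret), drop = FALSE]
  sel <- parsimonious_select(F_, threshold = threshold,
                             max_points = max_points)
  sel$dimension
}
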