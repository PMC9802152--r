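#' Diffusion maps with density normalization
#'
#' Builds the diffusion-map embedding of a point cloud: Gaussian kernel
#' `W_ij = exp(-||x_i - x_j||^2 / epsilon)`, density normalization
#' `W / (q_i^alpha q_j^alpha)` with `q = rowSums(W)` (`alpha = 1` removes the
#' sampling-density bias), row normalization to a Markov matrix, and a
#' symmetric eigendecomposition of its conjugate. The leading eigenpair is
#' `(1, constant)`; subsequent eigenvectors, ordered by descending eigenvalue,
#' provide candidate intrinsic coordinates. Signs are fixed so that the first
#' entry of each eigenvector exceeding `1e-10` in magnitude is positive,
#' making the decomposition deterministic.
#'
#' When the kernel is built on behavior (output) vectors the embedding
#' coordinates parameterize the model manifold; this is the "output-informed"
#' usage (see [intrinsic_dimension()]).
#'
#' @param X numeric matrix or data frame, one point per row.
#' @param epsilon kernel scale; default [choose_epsilon()] median rule.
#' @param alpha density-normalization exponent (default 1; 0 gives the plain
#'   normalized graph Laplacian convention).
#' @param m number of nontrivial eigenpairs to retain (default 20).
#' @return Object of class `dmaps`: eigenvalues (`lambda0 = 1` first),
#'   eigenvector matrix (columns `phi0, phi1, ...`), kernel metadata, and the
#'   training points (needed by [nystrom_extend()]).
#' @export
#' @examples
#' theta <- seq(0, 2 * pi, length.out = 200)[-1]
#' dm <- dmaps_fit(cbind(cos(theta), sin(theta)), m = 5)
#' dm$eigenvalues[1]
dmaps_fit <- function(X, epsilon = NULL, alpha = 1, m = 20) {
  X <- as_matrix(X)
  n <- nrow(X)
  if (n < m + 2) abort("need at least m + 2 points")
  D2 <- sq_dist(X)
  if (is.null(epsilon)) epsilon <- choose_epsilon(sqrt(D2))
  if (epsilon <= 0) abort("epsilon must be positive")
  W <- exp(-D2 / epsilon)
  q <- rowSums(W)
  if (any(q - 1 < 1e-14)) {
    abort("kernel is numerically diagonal: epsilon too small for this point cloud")
  }
  if (alpha != 0) {
    W <- W / outer(q^alpha, q^alpha)
  }
  d <- rowSums(W)
  sq <- sqrt(d)
  A <- W / outer(sq, sq)
  A <- (A + t(A)) / 2
  eig <- eigen(A, symmetric = TRUE)
  keep <- seq_len(min(m + 1L, n))
  vals <- eig$values[keep]
  vecs <- eig$vectors[, keep, drop = FALSE]
  phi <- vecs / sq
  # normalize so the trivial eigenvector is exactly 1
  phi <- phi / phi[1, 1]
  phi <- fix_signs(phi)
  colnames(phi) <- paste0("phi", keep - 1L)
  structure(
    list(X = X, epsilon = epsilon, alpha = alpha, m = length(keep) - 1L,
         eigenvalues = vals, vectors = phi, q = q),
    class = "dmaps")
}

fix_signs <- function(V, tol = 1e-10) {
  for (j in seq_len(ncol(V))) {
    i <- which(abs(V[, j]) > tol)[1]
    if (!is.na(i) && V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

#' @export
print.dmaps <- function(x, ...) {
  cat(sprintf("<dmaps> n = %d, D = %d, epsilon = %.4g, alpha = %g, m = %d\n",
              nrow(x$X), ncol(x$X), x$epsilon, x$alpha, x$m))
  invisible(x)
}

#' Kernel-scale selection
#'
#' `"median"` (default) returns the median of the squared pairwise distances;
#' `"plateau"` scans the log-log curve of the total kernel sum
#' `S(eps) = sum_ij exp(-d_ij^2/eps)`, which interpolates between `n`
#' (numerically diagonal kernel) and `n^2` (flat kernel), and returns the
#' scale at which its slope has fallen to half of its maximum -- the onset of
#' the saturation plateau, where the kernel resolves the full point cloud.
#'
#' @param distances Euclidean distance matrix (or `dist` object) between
#'   points.
#' @param rule `"median"` or `"plateau"`.
#' @return Positive kernel scale (on the squared-distance scale).
#' @export
choose_epsilon <- function(distances, rule = c("median", "plateau")) {
  rule <- match.arg(rule)
  D <- as.matrix(distances)
  off <- D[upper.tri(D)]
  if (length(off) == 0) abort("need at least two points")
  if (rule == "median") {
    eps <- median(off^2)
    if (eps <= 0) abort("median pairwise distance is zero (duplicate-only data)")
    return(eps)
  }
  d2 <- off^2
  n <- nrow(D)
  grid <- exp(seq(log(max(min(d2[d2 > 0]), 1e-12)), log(max(d2) * 10),
                  length.out = 80))
  logS <- vapply(grid, function(e) log(2 * sum(exp(-d2 / e)) + n), 0)
  slope <- diff(logS) / diff(log(grid))
  mids <- exp((log(grid[-1]) + log(grid[-length(grid)])) / 2)
  peak <- which.max(slope)
  after <- which(slope[peak:length(slope)] < max(slope) / 2)
  if (length(after) == 0) return(mids[length(mids)])
  mids[after[1] + peak - 1L]
}

#' Parsimonious (nonharmonic) eigenvector selection
#'
#' Higher diffusion-map eigenvectors are often harmonics -- functions of
#' earlier ones -- rather than new directions on the manifold. Each candidate
#' eigenvector `phi_k` (`k >= 2`) is regressed on the previously *retained*
#' eigenvectors by Gaussian-weighted local linear regression (bandwidth =
#' median pairwise distance of the retained coordinates / 3) with
#' leave-one-out prediction; the normalized residual
#' `r_k = sqrt(sum (phi_k - hat phi_k)^2 / sum phi_k^2)` is close to 0 for
#' harmonics and close to 1 for genuinely new directions. Eigenvectors with
#' `r_k > threshold` are retained as they are met, in eigenvalue order;
#' `phi_1` is always retained (`r_1 = 1` by convention). Regressing on the
#' retained set only (rather than on all previous eigenvectors) keeps weak
#' independent directions detectable when they surface deep in the spectrum
#' of a strongly anisotropic manifold.
#'
#' Candidates whose eigenvalue has decayed below `lambda_floor` times the
#' first nontrivial eigenvalue are excluded: such modes are dominated by
#' finite-sample quadrature noise (they are typically localized spikes) and
#' would otherwise masquerade as new directions.
#'
#' The retained count estimates the manifold's dimension for function-like
#' (single-chart) data; closed manifolds such as a circle need more embedding
#' coordinates than their dimension.
#'
#' @param model a `dmaps` object, or a matrix of nontrivial eigenvectors
#'   (columns `phi_1, phi_2, ...`).
#' @param threshold retention threshold in (0, 1) (default 0.5).
#' @param n_check number of leading nontrivial eigenvectors to score
#'   (default `min(12, available)`).
#' @param max_points subsample size for the local regressions (default 2000);
#'   rows are taken evenly spaced, deterministically.
#' @param lambda_floor relative eigenvalue floor for candidates (default
#'   `1e-6`; only applied when `model` is a `dmaps` object).
#' @return List with `indices` (retained nontrivial indices), `residuals`,
#'   `threshold` and `dimension = length(indices)`.
#' @export
parsimonious_select <- function(model, threshold = 0.5, n_check = NULL,
                                max_points = 2000, lambda_floor = 1e-6) {
  if (threshold <= 0 || threshold >= 1) abort("threshold must lie in (0, 1)")
  lambdas <- NULL
  if (inherits(model, "dmaps")) {
    Phi <- model$vectors[, -1, drop = FALSE]
    lambdas <- abs(model$eigenvalues[-1])
  } else {
    Phi <- as_matrix(model)
  }
  if (ncol(Phi) < 2) abort("need at least two nontrivial eigenvectors")
  if (is.null(n_check)) n_check <- min(12L, ncol(Phi))
  n_check <- min(n_check, ncol(Phi))
  if (!is.null(lambdas)) {
    n_check <- min(n_check, max(1L, sum(lambdas >= lambda_floor * lambdas[1])))
  }
  n <- nrow(Phi)
  idx <- if (n > max_points) round(seq(1, n, length.out = max_points)) else seq_len(n)
  Phi <- Phi[idx, seq_len(n_check), drop = FALSE]
  n <- nrow(Phi)
  r <- numeric(n_check)
  r[1] <- 1
  retained <- 1L
  if (n_check >= 2) for (k in 2:n_check) {
    U <- Phi[, retained, drop = FALSE]
    y <- Phi[, k]
    D2u <- sq_dist(U)
    h <- median(sqrt(D2u[upper.tri(D2u)])) / 3
    if (h <= 0) { r[k] <- 0; next }
    Wk <- exp(-D2u / h^2)
    diag(Wk) <- 0  # leave-one-out
    pred <- numeric(n)
    for (i in seq_len(n)) {
      w <- Wk[i, ]
      Xd <- cbind(1, sweep(U, 2, U[i, ]))
      Xw <- Xd * w
      XtX <- crossprod(Xw, Xd)
      beta <- tryCatch(solve(XtX, crossprod(Xw, y)),
                       error = function(e) NULL)
      pred[i] <- if (!is.null(beta) && is.finite(beta[1])) beta[1]
                 else if (any(w > 0)) sum(w * y) / sum(w)
                 else 0  # isolated point: nothing to predict from
    }
    r[k] <- min(1, sqrt(sum((y - pred)^2) / sum(y^2)))
    if (!is.finite(r[k])) r[k] <- 0
    if (r[k] > threshold) retained <- c(retained, k)
  }
  list(indices = retained, residuals = r, threshold = threshold,
       dimension = length(retained))
}

#' Nystrom out-of-sample extension of diffusion-map coordinates
#'
#' Evaluates the trained eigenvectors at new points through the same
#' normalized kernel: `phi_k(x) = lambda_k^{-1} sum_i P(x, x_i) phi_k(x_i)`.
#' At a training point this reproduces the stored eigenvector entries to
#' numerical precision. Points whose nearest training squared distance
#' exceeds `guard * epsilon` trigger an extrapolation warning.
#'
#' @param model a fitted `dmaps` object.
#' @param x_new matrix (or vector) of new points in the training ambient
#'   space.
#' @param guard extrapolation guard multiplier (default 9).
#' @return Matrix `n_new x (m + 1)` of extended eigenvector values (including
#'   the trivial `phi0 = 1` column).
#' @export
nystrom_extend <- function(model, x_new, guard = 9) {
  stopifnot(inherits(model, "dmaps"))
  if (is.null(dim(x_new))) x_new <- matrix(x_new, nrow = 1)
  x_new <- as_matrix(x_new)
  D2 <- sq_dist(x_new, model$X)
  nearest <- apply(D2, 1, min)
  if (any(nearest > guard * model$epsilon)) {
    warn(sprintf("%d point(s) lie far from the training data (min squared distance > %g * epsilon); Nystrom values are extrapolations",
                 sum(nearest > guard * model$epsilon), guard))
  }
  K <- exp(-D2 / model$epsilon)
  if (model$alpha != 0) {
    qn <- rowSums(K)
    K <- K / outer(qn^model$alpha, model$q^model$alpha)
  }
  P <- K / rowSums(K)
  ext <- P %*% model$vectors
  ext <- sweep(ext, 2, model$eigenvalues, "/")
  colnames(ext) <- colnames(model$vectors)
  ext
}

#' Intrinsic dimension of an ensemble dataset
#'
#' Counts the effective parameter combinations of a sampled input-output
#' system. In `"output_informed"` mode the kernel is built on the behavior
#' vectors, so the retained-eigenvector count is the dimension of the model
#' manifold -- the number of parameter combinations the output depends on. In
#' `"parameter_space"` mode the kernel is built on the (column-standardized)
#' parameter vectors, the natural mode for an equivalent-optima ensemble,
#' where the count is the number of redundant combinations spanning the level
#' set.
#'
#' Distinguishing one thin manifold direction from another requires a kernel
#' scale choice suited to *counting* rather than embedding: with the default
#' `scale_rule = "global"` the kernel scale is set to half the squared
#' diameter of the point cloud. In this wide-kernel regime the eigenvalue
#' decay per independent direction is geometric, so a direction two orders of
#' magnitude thinner than the leading one still surfaces within the first
#' ~10 eigenvectors (at a logarithmically compressed index) instead of at an
#' unreachably deep position as it would under a locality-scaled kernel
#' (`scale_rule = "median"`).
#'
#' @param dataset an [ensemble_dataset()].
#' @param mode `"output_informed"` (default) or `"parameter_space"`.
#' @param threshold parsimonious retention threshold.
#' @param m number of candidate eigenpairs.
#' @param epsilon optional kernel scale override (disables `scale_rule`).
#' @param scale_rule `"global"` (default; half squared diameter) or
#'   `"median"` ([choose_epsilon()] median rule).
#' @param n_max subsample cap for the diffusion map (default 6000).
#' @param max_points subsample cap for the parsimonious regressions.
#' @return List with `dimension`, the fitted `model`, the `selection` report
#'   from [parsimonious_select()], and `rows`, the subsample indices used.
#' @export
intrinsic_dimension <- function(dataset, mode = c("output_informed", "parameter_space"),
                                threshold = 0.5, m = 20, epsilon = NULL,
                                scale_rule = c("global", "median"),
                                n_max = 6000, max_points = 2000) {
  mode <- match.arg(mode)
  scale_rule <- match.arg(scale_rule)
  stopifnot(inherits(dataset, "ensemble_dataset"))
  X <- if (mode == "output_informed") as_matrix(dataset$behaviors)
       else scale(as_matrix(dataset$parameters))
  n <- nrow(X)
  rows <- if (n > n_max) round(seq(1, n, length.out = n_max)) else seq_len(n)
  X <- X[rows, , drop = FALSE]
  if (is.null(epsilon) && scale_rule == "global") {
    D2 <- sq_dist(X)
    epsilon <- 0.5 * max(D2)
  }
  model <- dmaps_fit(X, epsilon = epsilon, m = m)
  sel <- parsimonious_select(model, threshold = threshold,
                             max_points = max_points)
  list(dimension = sel$dimension, model = model, selection = sel, mode = mode,
       rows = rows)
}

#' Explained-variance ratios of principal components
#'
#' @param Y matrix or data frame (rows = samples).
#' @param scale standardize columns first (default `FALSE`).
#' @return Numeric vector of variance ratios, descending, summing to 1.
#' @export
pca_explained <- function(Y, scale = FALSE) {
  p <- prcomp(as_matrix(Y), center = TRUE, scale. = scale)
  v <- p$sdev^2
  v / sum(v)
}
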