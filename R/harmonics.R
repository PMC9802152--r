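#' Geometric-harmonics interpolation
#'
#' Extends a function known on sampled points to new points through the
#' eigenfunctions of a Gaussian kernel: with `K_ij = exp(-||x_i - x_j||^2 /
#' epsilon)` and eigenpairs `(sigma_l, psi_l)`, the interpolant is
#' `f(x) = sum_l sigma_l^{-1} (sum_i k(x, x_i) psi_l(x_i)) <f, psi_l>`
#' over the eigenpairs with `sigma_l >= delta * sigma_0`. Fitting is a
#' projection: evaluation at a training point returns the component of the
#' training values inside the retained span.
#'
#' @param points numeric matrix of training inputs (one per row).
#' @param values numeric vector or matrix of training outputs (multi-output
#'   targets are fitted component-wise against the shared basis).
#' @param epsilon kernel scale; default = median of squared pairwise
#'   distances.
#' @param delta spectral cutoff relative to the leading kernel eigenvalue
#'   (default `1e-8`); must be < 1.
#' @return Object of class `geometric_harmonics`.
#' @export
gh_fit <- function(points, values, epsilon = NULL, delta = 1e-8) {
  points <- as_matrix(points)
  values <- as_matrix(values)
  if (nrow(points) != nrow(values)) abort("points and values must align")
  if (delta >= 1) abort("delta must be < 1: nothing would be retained")
  D2 <- sq_dist(points)
  if (is.null(epsilon)) epsilon <- median(D2[upper.tri(D2)])
  K <- exp(-D2 / epsilon)
  eig <- eigen(K, symmetric = TRUE)
  sigma <- eig$values
  keep <- which(sigma >= delta * sigma[1] & sigma > 0)
  psi <- eig$vectors[, keep, drop = FALSE]
  coef <- crossprod(psi, values)
  structure(
    list(points = points, epsilon = epsilon, delta = delta,
         sigma = sigma[keep], psi = psi, coef = coef,
         out_names = colnames(values)),
    class = "geometric_harmonics")
}

#' @export
print.geometric_harmonics <- function(x, ...) {
  cat(sprintf("<geometric_harmonics> n = %d, retained %d eigenpairs, epsilon = %.4g\n",
              nrow(x$points), length(x$sigma), x$epsilon))
  invisible(x)
}

#' Evaluate a geometric-harmonics interpolant
#'
#' @param object a `geometric_harmonics` fit.
#' @param newdata matrix (or vector) of evaluation points.
#' @param ... unused.
#' @return Matrix of interpolated values (rows = points).
#' @export
predict.geometric_harmonics <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  Kn <- exp(-sq_dist(as_matrix(newdata), object$points) / object$epsilon)
  psi_new <- sweep(Kn %*% object$psi, 2, object$sigma, "/")
  out <- psi_new %*% object$coef
  colnames(out) <- object$out_names
  out
}

#' Double DMaps: geometric harmonics in diffusion-map coordinates
#'
#' Interpolates functions defined on a manifold by working in the retained
#' diffusion-map coordinates `phi` rather than the ambient space: a second
#' kernel eigendecomposition on `phi` provides the geometric-harmonics basis,
#' giving well-conditioned interpolation of functions of the reduced
#' coordinates. Composed with [nystrom_extend()], this yields fully
#' out-of-sample prediction: ambient point -> `phi` -> interpolated value.
#'
#' @param model a fitted [dmaps_fit()] object.
#' @param values training outputs (vector or matrix), one row per training
#'   point of `model`.
#' @param indices nontrivial eigenvector indices to use as coordinates;
#'   default: parsimonious selection on `model`.
#' @param eps_factor the geometric-harmonics kernel scale is `eps_factor`
#'   times the median squared pairwise distance in `phi` space (default 1).
#' @param delta spectral cutoff (default `1e-8`; the kernel spectrum decays
#'   fast in the low-dimensional `phi` coordinates, and a deep cutoff keeps
#'   enough eigenpairs for sub-0.1 percent interpolation).
#' @return Object of class `double_dmaps`.
#' @export
double_dmaps_fit <- function(model, values, indices = NULL, eps_factor = 1,
                             delta = 1e-8) {
  stopifnot(inherits(model, "dmaps"))
  if (is.null(indices)) indices <- parsimonious_select(model)$indices
  Phi <- model$vectors[, indices + 1L, drop = FALSE]
  D2 <- sq_dist(Phi)
  eps <- eps_factor * median(D2[upper.tri(D2)])
  fit <- gh_fit(Phi, values, epsilon = eps, delta = delta)
  structure(
    list(dmaps = model, indices = indices, gh = fit),
    class = "double_dmaps")
}

#' Evaluate a Double DMaps interpolant
#'
#' @param object a `double_dmaps` fit.
#' @param newdata matrix of diffusion-map coordinates (columns matching the
#'   retained indices), or `NULL` to use `ambient`.
#' @param ambient matrix of new points in the original ambient space; they
#'   are first mapped to diffusion coordinates with [nystrom_extend()].
#' @param ... unused.
#' @return Matrix of predicted values.
#' @export
predict.double_dmaps <- function(object, newdata = NULL, ambient = NULL, ...) {
  if (is.null(newdata)) {
    if (is.null(ambient)) abort("supply either `newdata` (phi) or `ambient`")
    ext <- nystrom_extend(object$dmaps, ambient)
    newdata <- ext[, object$indices + 1L, drop = FALSE]
  }
  predict(object$gh, newdata)
}

#' Fit the two directed maps of a behavior/effective-parameter ensemble
#'
#' From one ensemble (effective parameters paired with behaviors) this builds
#' both data-driven directions:
#' \describe{
#'   \item{predict}{a diffusion map on the effective parameters plus a Double
#'     DMaps interpolant of the behaviors, used by [predict_behavior()];}
#'   \item{estimate}{an output-informed diffusion map on the behaviors plus a
#'     Double DMaps interpolant of the effective parameters, used by
#'     [estimate_effective_parameters()].}
#' }
#'
#' @param dataset an [ensemble_dataset()] (e.g. [sample_kappa_dataset()]).
#' @param directions subset of `c("predict", "estimate")`.
#' @param m,epsilon,eps_factor,delta tuning passed to [dmaps_fit()] /
#'   [double_dmaps_fit()].
#' @param indices optional fixed nontrivial eigenvector indices (default:
#'   parsimonious selection per direction).
#' @return Object of class `behavior_map`.
#' @export
fit_behavior_map <- function(dataset, directions = c("predict", "estimate"),
                             m = 10, epsilon = NULL, eps_factor = 1,
                             delta = 1e-8, indices = NULL) {
  stopifnot(inherits(dataset, "ensemble_dataset"))
  K <- as_matrix(dataset$parameters)
  B <- as_matrix(dataset$behaviors)
  out <- list(par_names = colnames(K), times = dataset$meta$times,
              par_range = apply(K, 2, range))
  if ("predict" %in% directions) {
    # the parameter box is full-rank, so a locality-scaled kernel suffices
    dm_k <- dmaps_fit(K, epsilon = epsilon, m = m)
    out$predict <- double_dmaps_fit(dm_k, B, indices = indices,
                                    eps_factor = eps_factor, delta = delta)
  }
  if ("estimate" %in% directions) {
    # the behavior manifold is strongly anisotropic: use the global counting
    # scale so weak directions surface among the leading eigenvectors, keep
    # as many nonharmonic coordinates as there are effective parameters, and
    # widen the interpolation kernel for smoother extension
    eps_b <- epsilon
    if (is.null(eps_b)) eps_b <- 0.5 * max(sq_dist(B))
    dm_b <- dmaps_fit(B, epsilon = eps_b, m = max(m, 15))
    idx_b <- indices
    if (is.null(idx_b)) {
      idx_b <- head(parsimonious_select(dm_b)$indices, ncol(K))
    }
    out$estimate <- double_dmaps_fit(dm_b, K, indices = idx_b,
                                     eps_factor = 4 * eps_factor,
                                     delta = delta)
  }
  structure(out, class = "behavior_map")
}

#' Predict output behavior from new effective-parameter values
#'
#' Maps new effective-parameter vectors to the predicted output time series
#' via Nystrom extension into the parameter-side diffusion map and Double
#' DMaps interpolation. Values outside the sampled parameter box trigger an
#' extrapolation warning.
#'
#' @param map a [fit_behavior_map()] object with the `"predict"` direction.
#' @param kappa_new matrix / data frame / named vector of new
#'   effective-parameter values.
#' @return Tibble of predicted behavior vectors (columns = time points).
#' @export
predict_behavior <- function(map, kappa_new) {
  stopifnot(inherits(map, "behavior_map"))
  if (is.null(map$predict)) abort("map was fitted without the 'predict' direction")
  if (is.null(dim(kappa_new))) kappa_new <- matrix(kappa_new, nrow = 1,
                                                   dimnames = list(NULL, names(kappa_new)))
  Kn <- as_matrix(kappa_new)
  rng <- map$par_range
  below <- sweep(Kn, 2, rng[1, ], "<")
  above <- sweep(Kn, 2, rng[2, ], ">")
  if (any(below | above)) {
    warn(sprintf("%d point(s) outside the sampled effective-parameter range; predictions are extrapolations",
                 sum(rowSums(below | above) > 0)))
  }
  out <- predict(map$predict, ambient = Kn)
  as_tibble(as.data.frame(out))
}

#' Estimate effective parameters from a new, unobserved behavior
#'
#' Projects a new behavior vector onto the model manifold via Nystrom
#' extension of the output-informed diffusion map and reads off the effective
#' parameters with Double DMaps. Behaviors far from the training manifold
#' (nearest squared distance beyond `guard * epsilon`) are rejected as
#' out-of-manifold.
#'
#' @param map a [fit_behavior_map()] object with the `"estimate"` direction.
#' @param behavior_new matrix or vector of new behavior observations.
#' @param guard out-of-manifold rejection multiplier (default 9).
#' @return Tibble of estimated effective-parameter vectors.
#' @export
estimate_effective_parameters <- function(map, behavior_new, guard = 9) {
  stopifnot(inherits(map, "behavior_map"))
  if (is.null(map$estimate)) abort("map was fitted without the 'estimate' direction")
  if (is.null(dim(behavior_new))) behavior_new <- matrix(behavior_new, nrow = 1)
  Bn <- as_matrix(behavior_new)
  dm <- map$estimate$dmaps
  nearest <- apply(sq_dist(Bn, dm$X), 1, min)
  if (any(nearest > guard * dm$epsilon)) {
    abort(sprintf("behavior lies off the sampled model manifold (nearest squared distance %.3g > %g * epsilon = %.3g)",
                  max(nearest), guard, guard * dm$epsilon))
  }
  out <- predict(map$estimate, ambient = Bn)
  colnames(out) <- map$par_names
  as_tibble(as.data.frame(out))
}

#' Per-point Jacobian determinants of a learned map
#'
#' Central finite differences of `f` at each point, with steps equal to
#' `step_frac` times the per-coordinate range of `points`. A determinant
#' bounded away from zero over the data certifies local invertibility of the
#' map (inverse function theorem).
#'
#' @param f function taking a matrix of inputs (rows = points) and returning
#'   a matrix of outputs with the same number of columns as the input.
#' @param points matrix of evaluation points.
#' @param step_frac relative finite-difference step (default `1e-4`).
#' @return Numeric vector of determinants, one per row of `points`.
#' @export
jacobian_determinant <- function(f, points, step_frac = 1e-4) {
  X <- as_matrix(points)
  d <- ncol(X)
  rng <- apply(X, 2, function(col) diff(range(col)))
  rng[rng == 0] <- 1
  h <- step_frac * rng
  cols <- vector("list", d)
  for (j in seq_len(d)) {
    Xp <- X; Xp[, j] <- Xp[, j] + h[j]
    Xm <- X; Xm[, j] <- Xm[, j] - h[j]
    cols[[j]] <- (f(Xp) - f(Xm)) / (2 * h[j])  # d f / d x_j, n x d_out
  }
  d_out <- ncol(cols[[1]])
  if (d_out != d) abort("jacobian_determinant requires a square map")
  vapply(seq_len(nrow(X)), function(i) {
    J <- vapply(cols, function(cj) cj[i, ], numeric(d_out))
    det(J)
  }, 0)
}
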