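#' Ensemble datasets
#'
#' An ensemble dataset pairs a table of parameter vectors with the behaviors
#' (fixed-length output vectors on a common time grid) they produce, plus the
#' provenance needed to regenerate it: base point, perturbation fraction,
#' observation times, observable and seed.
#'
#' @param parameters data frame / matrix, one parameter vector per row.
#' @param behaviors data frame / matrix, one behavior vector per row,
#'   row-aligned with `parameters`.
#' @param base named base parameter point (or `NULL`).
#' @param fraction perturbation fraction used to generate `parameters`.
#' @param times observation times of the behavior entries.
#' @param observable name of the observed quantity.
#' @param seed RNG seed used in generation.
#' @return An object of class `ensemble_dataset`: a list with tibbles
#'   `parameters` and `behaviors` and a `meta` list.
#' @export
ensemble_dataset <- function(parameters, behaviors, base = NULL, fraction = NA,
                             times = NULL, observable = NA_character_,
                             seed = NULL) {
  parameters <- as_tibble(as.data.frame(parameters))
  behaviors <- as_tibble(as.data.frame(behaviors))
  if (nrow(parameters) != nrow(behaviors)) {
    abort("parameters and behaviors must have the same number of rows")
  }
  if (nrow(parameters) == 0) abort("ensemble must contain at least one row")
  if (anyNA(parameters) || anyNA(behaviors)) {
    abort("ensemble contains missing values")
  }
  if (any(!is.finite(as_matrix(behaviors)))) {
    abort("ensemble behaviors contain non-finite values")
  }
  structure(
    list(parameters = parameters, behaviors = behaviors,
         meta = list(base = base, fraction = fraction, times = times,
                     observable = observable, seed = seed)),
    class = "ensemble_dataset")
}

#' @export
print.ensemble_dataset <- function(x, ...) {
  cat(sprintf("<ensemble_dataset> %d samples: %d parameters -> %d-point behavior (%s)\n",
              nrow(x$parameters), ncol(x$parameters), ncol(x$behaviors),
              x$meta$observable))
  invisible(x)
}

#' Uniform box sampling around a base parameter point
#'
#' Each parameter is drawn independently and uniformly within `+/- fraction`
#' of its base value; the perturbations are a device for sampling the
#' neighborhood of the base point in parameter space.
#'
#' @param base named positive base parameter vector.
#' @param fraction half-width of the relative perturbation box (`0 <= fraction < 1`).
#' @param n number of samples.
#' @param seed RNG seed (optional but recommended).
#' @return A tibble with `n` rows and one column per parameter.
#' @export
#' @examples
#' sample_parameters(msp_base_point(), fraction = 0.1, n = 5, seed = 1)
sample_parameters <- function(base, fraction, n, seed = NULL) {
  if (n <= 0) abort("n must be positive")
  if (fraction < 0 || fraction >= 1) abort("fraction must lie in [0, 1)")
  base <- unlist(base)
  if (any(base <= 0)) abort("base parameters must be positive")
  P <- length(base)
  draws <- with_seed(seed, matrix(runif(n * P, -1, 1), n, P))
  X <- sweep(1 + fraction * draws, 2, base, "*")
  colnames(X) <- names(base)
  as_tibble(as.data.frame(X))
}

behavior_simulator <- function(model, ic, times, observable) {
  switch(model,
    msp = function(p) simulate_msp(p, ic = ic, times = times)[[observable]],
    caricature = function(p) simulate_caricature(p, ic = ic, times = times)[[observable]],
    reduced = function(p) simulate_reduced(p, ic = ic, times = times)[[observable]],
    abort(sprintf("unknown model '%s'", model)))
}

#' Build a transient ensemble: simulate each parameter vector
#'
#' Runs the forward model for every row of `parameters` and records the chosen
#' observable on the time grid, yielding the paired parameter/behavior
#' ensemble whose behavior rows sample the model manifold.
#'
#' @param parameters data frame of parameter vectors (e.g. from
#'   [sample_parameters()]).
#' @param model `"msp"`, `"caricature"`, `"reduced"`, or a function
#'   `p -> numeric behavior vector` for black-box systems.
#' @param ic initial state passed to the built-in simulators.
#' @param times observation times.
#' @param observable species name to record (ignored for function models).
#' @param base,fraction,seed provenance recorded in the dataset meta.
#' @return An [ensemble_dataset()].
#' @export
build_transient_dataset <- function(parameters, model = "msp",
                                    ic = NULL, times = seq(2, 20, by = 2),
                                    observable = "S2", base = NULL,
                                    fraction = NA, seed = NULL) {
  pm <- as_matrix(parameters)
  sim <- if (is.function(model)) {
    model
  } else {
    if (is.null(ic)) {
      ic <- if (model == "caricature") caricature_initial_state()
            else if (model == "reduced") c(S0 = 5, S1 = 0, S2 = 0)
            else msp_initial_state()
    }
    behavior_simulator(model, ic, times, observable)
  }
  rows <- vector("list", nrow(pm))
  for (i in seq_len(nrow(pm))) {
    p <- pm[i, ]
    names(p) <- colnames(pm)
    rows[[i]] <- sim(p)
  }
  B <- do.call(rbind, rows)
  colnames(B) <- paste0("t", seq_len(ncol(B)))
  ensemble_dataset(parameters, B, base = base, fraction = fraction,
                   times = times, observable = observable, seed = seed)
}

#' Equivalent-optima ensemble: refit the reference transient from random starts
#'
#' Reproduces the construction of the "optimization" dataset: the reference
#' output transient is generated at the base point, then all model parameters
#' are refit by bound-constrained nonlinear least squares
#' (Levenberg-Marquardt in log10-parameter space) from starting points drawn
#' log10-uniformly within `10^-bounds_decades` and `10^+bounds_decades` times
#' the base rates. Fits whose relative RMS residual (relative to the RMS of
#' the reference behavior) is at most `threshold` are accepted; each accepted
#' parameter vector therefore reproduces the reference behavior to within the
#' threshold, i.e. lies on the level set of the reference behavior.
#'
#' @param base named base parameter vector (default [msp_base_point()]).
#' @param n_starts number of random starting points (default 1000).
#' @param bounds_decades half-width, in decades, of the sampling/fit box.
#' @param threshold acceptance threshold on the relative RMS residual.
#' @param ic,times,observable forward-model settings (defaults: the reference
#'   initial condition and `[S2]` at `t = 2, 4, ..., 20`).
#' @param seed RNG seed for the starting points.
#' @param maxiter maximum Levenberg-Marquardt iterations per start.
#' @param epsfcn forward-difference step factor for the numerical Jacobian;
#'   must exceed the ODE-solver noise floor or the optimizer stalls in the
#'   sloppy valleys (default `1e-6`).
#' @return An [ensemble_dataset()] of accepted fits; `meta$n_starts`,
#'   `meta$residuals` record provenance. Errors if no fit is accepted.
#' @export
build_optimization_dataset <- function(base = msp_base_point(), n_starts = 1000,
                                       bounds_decades = 3, threshold = 1e-4,
                                       ic = msp_initial_state(),
                                       times = seq(2, 20, by = 2),
                                       observable = "S2", seed = NULL,
                                       maxiter = 150, epsfcn = 1e-6) {
  base <- unlist(base)
  sim <- behavior_simulator("msp", ic, times, observable)
  reference <- sim(base)
  ref_rms <- sqrt(mean(reference^2))
  lb <- log10(base) - bounds_decades
  ub <- log10(base) + bounds_decades
  starts <- with_seed(seed, {
    matrix(runif(n_starts * length(base), rep(lb, each = n_starts),
                 rep(ub, each = n_starts)), n_starts, length(base))
  })
  resid_fn <- function(logp) {
    p <- 10^logp
    names(p) <- names(base)
    out <- tryCatch(sim(p), error = function(e) NULL)
    if (is.null(out)) return(rep(1e3 * ref_rms, length(reference)))
    out - reference
  }
  accepted <- list()
  resids <- numeric(0)
  for (i in seq_len(n_starts)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], lower = lb, upper = ub,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter, epsfcn = epsfcn)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rel <- sqrt(mean(fit$fvec^2)) / ref_rms
    if (is.finite(rel) && rel <= threshold) {
      accepted[[length(accepted) + 1L]] <- 10^fit$par
      resids <- c(resids, rel)
    }
  }
  if (length(accepted) == 0) {
    abort("no least-squares fit met the acceptance threshold; loosen `threshold` or increase `n_starts`")
  }
  P <- do.call(rbind, accepted)
  colnames(P) <- names(base)
  B <- do.call(rbind, lapply(seq_len(nrow(P)), function(i) {
    p <- P[i, ]; names(p) <- names(base); sim(p)
  }))
  colnames(B) <- paste0("t", seq_len(ncol(B)))
  ds <- ensemble_dataset(P, B, base = base, fraction = NA, times = times,
                         observable = observable, seed = seed)
  ds$meta$n_starts <- n_starts
  ds$meta$threshold <- threshold
  ds$meta$residuals <- resids
  ds$meta$reference <- reference
  ds
}

#' Nominal effective-parameter triplet
#'
#' The reference `(kappa1, kappa2, pi) = (0.467, 0.232, 0.362)` around which
#' the reduced-model ensembles are sampled.
#' @return Named numeric triplet.
#' @export
kappa_nominal <- function() c(kappa1 = 0.467, kappa2 = 0.232, pi = 0.362)

#' Ensemble of reduced-model behaviors over effective-parameter triplets
#'
#' Samples `(kappa1, kappa2, pi)` uniformly within `+/- fraction` of the
#' nominal triplet and records the reduced-model `S2` trajectory for each.
#'
#' @param nominal named nominal triplet (default [kappa_nominal()]).
#' @param fraction relative perturbation half-width (default 0.2).
#' @param n number of triplets (default 5000).
#' @param times observation times (default `2, 4, ..., 20`).
#' @param seed RNG seed.
#' @return An [ensemble_dataset()] with 3-column parameters and 10-column
#'   behaviors.
#' @export
sample_kappa_dataset <- function(nominal = kappa_nominal(), fraction = 0.2,
                                 n = 5000, times = seq(2, 20, by = 2),
                                 seed = NULL) {
  K <- sample_parameters(nominal, fraction, n, seed = seed)
  build_transient_dataset(K, model = "reduced", ic = c(S0 = 5, S1 = 0, S2 = 0),
                          times = times, observable = "S2", base = nominal,
                          fraction = fraction, seed = seed)
}

#' Paired datasets for jointly-smooth-function extraction
#'
#' Builds the two row-aligned views used by [jsf_extract()]: `X1` holds
#' `n_delays` consecutive time samples of each listed species concatenated
#' into one long measurement vector per parameter setting, and `X2` holds the
#' corresponding parameter vectors. Optionally the latter half of the
#' measurement columns is replaced by uniform noise over each column's
#' observed range, to probe robustness to uninformative outputs.
#'
#' @param parameters data frame of parameter vectors.
#' @param model `"caricature"` (default) or `"msp"`.
#' @param ic initial state (defaults per model).
#' @param species species to record (default `c("S0", "S1", "C", "E")`, the
#'   substrate states, complex and free enzyme of the caricature).
#' @param n_delays number of consecutive time samples per species (default 20).
#' @param dt spacing of the time samples (default 2).
#' @param noise_half replace the latter half of measurement columns by uniform
#'   noise over the column range.
#' @param seed RNG seed for the noise substitution.
#' @return List with matrices `X1` (`n x length(species)*n_delays`) and `X2`
#'   (`n x P`), plus the time grid.
#' @export
build_jsf_pair <- function(parameters, model = "caricature", ic = NULL,
                           species = c("S0", "S1", "C", "E"), n_delays = 20,
                           dt = 2, noise_half = FALSE, seed = NULL) {
  pm <- as_matrix(parameters)
  times <- seq(dt, by = dt, length.out = n_delays)
  if (is.null(ic)) {
    ic <- if (model == "msp") msp_initial_state() else caricature_initial_state()
  }
  simfun <- if (model == "caricature") simulate_caricature else simulate_msp
  rows <- vector("list", nrow(pm))
  for (i in seq_len(nrow(pm))) {
    p <- pm[i, ]
    names(p) <- colnames(pm)
    tr <- simfun(p, ic = ic, times = times)
    rows[[i]] <- unlist(lapply(species, function(s) tr[[s]]))
  }
  X1 <- do.call(rbind, rows)
  colnames(X1) <- unlist(lapply(species, function(s) paste0(s, "_", seq_len(n_delays))))
  if (noise_half) {
    idx <- (ncol(X1) %/% 2 + 1L):ncol(X1)
    rng <- apply(X1[, idx, drop = FALSE], 2, range)
    noise <- with_seed(seed, {
      matrix(runif(nrow(X1) * length(idx), rep(rng[1, ], each = nrow(X1)),
                   rep(rng[2, ], each = nrow(X1))), nrow(X1), length(idx))
    })
    X1[, idx] <- noise
  }
  list(X1 = X1, X2 = pm, times = times, species = species,
       noise_half = noise_half)
}

#' Analytic two-parameter toy with a structurally nonidentifiable pair
#'
#' Samples `(p1, p2)` uniformly on the square `[0.5, 1.5]^2` and evaluates the
#' scalar output `f = exp(-p1 p2 / 2)`, which depends on the parameters only
#' through the effective combination `phi = p1 p2`; the conformal redundant
#' combination `psi = p1^2 - p2^2` parameterizes the level sets of `phi`
#' (`grad phi . grad psi = 0` everywhere).
#'
#' @param n number of samples.
#' @param seed RNG seed.
#' @param lower,upper sampling box for both parameters.
#' @return A tibble with columns `p1, p2, f, phi, psi`.
#' @export
toy_fig1_dataset <- function(n = 2000, seed = NULL, lower = 0.5, upper = 1.5) {
  if (n <= 0) abort("n must be positive")
  with_seed(seed, {
    p1 <- runif(n, lower, upper)
    p2 <- runif(n, lower, upper)
    tibble(p1 = p1, p2 = p2,
           f = exp(-p1 * p2 / 2),
           phi = p1 * p2,
           psi = p1^2 - p2^2)
  })
}
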