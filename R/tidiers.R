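#' Tidy a diffusion-map fit
#'
#' One row per eigenpair: index, eigenvalue, and (when a parsimonious
#' selection is supplied) the nonharmonic residual and retention flag.
#'
#' @param x a [dmaps_fit()] object.
#' @param selection optional [parsimonious_select()] result for `x`.
#' @param ... unused.
#' @return A tibble with columns `index`, `eigenvalue`, and optionally
#'   `residual`, `retained`.
#' @export
tidy.dmaps <- function(x, selection = NULL, ...) {
  out <- tibble(index = seq_along(x$eigenvalues) - 1L,
                eigenvalue = x$eigenvalues)
  if (!is.null(selection)) {
    res <- rep(NA_real_, nrow(out))
    res[seq_along(selection$residuals) + 1L] <- selection$residuals
    out$residual <- res
    out$retained <- out$index %in% selection$indices
  }
  out
}

#' @export
glance.dmaps <- function(x, ...) {
  tibble(n = nrow(x$X), ambient_dim = ncol(x$X), epsilon = x$epsilon,
         alpha = x$alpha, m = x$m)
}

#' Tidy a JSF basis: one row per extracted function
#'
#' @param x a [jsf_extract()] object.
#' @param ... unused.
#' @return A tibble with `index`, `score`, and `jointly_smooth` (score within
#'   10 percent of `sqrt(2)`).
#' @export
tidy.jsf_basis <- function(x, ...) {
  tibble(index = seq_along(x$scores), score = x$scores,
         jointly_smooth = x$scores >= 0.9 * sqrt(2))
}

#' @export
glance.jsf_basis <- function(x, ...) {
  tibble(n = x$n, d1 = x$d1, d2 = x$d2,
         n_jointly_smooth = suppressWarnings(jsf_score_gap(x$scores)))
}

#' Tidy a conformal-autoencoder training history
#'
#' @param x a [train_cae()] model.
#' @param ... unused.
#' @return The training history as a long tibble (`epoch`, `loss`, `value`).
#' @export
tidy.cae_model <- function(x, ...) {
  tidyr::pivot_longer(x$history, -"epoch", names_to = "loss",
                      values_to = "value")
}

#' @export
glance.cae_model <- function(x, ...) {
  tibble(n_latent = ncol(x$latents), n_eff = x$n_eff,
         reconstruction_mse = x$report$reconstruction_mse,
         behavior_mse = x$report$behavior_mse,
         orthogonality = x$report$orthogonality,
         seed = x$report$seed)
}
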