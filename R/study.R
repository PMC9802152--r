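#' End-to-end nonidentifiability study of the dual-phosphorylation model
#'
#' Regenerates the full analysis around the base point: a transient ensemble
#' (uniform parameter perturbations, `[S2]` observed on the time grid), its
#' output-informed intrinsic dimension; an equivalent-optima ensemble by
#' least-squares refitting, its parameter-space intrinsic dimension and top-3
#' PCA explained variance; and, optionally, the Double DMaps map from
#' data-driven coordinates to the analytical effective parameters with its
#' Jacobian-determinant invertibility check on a train/test split.
#'
#' @param n transient ensemble size (default 6000).
#' @param fraction perturbation half-width (default 0.1).
#' @param n_starts refit starts for the optimization ensemble (default 1000).
#' @param base base parameter point.
#' @param times observation times.
#' @param seed master seed; component seeds are derived from it.
#' @param components subset of `c("transient", "optimization", "maps")`.
#' @param test_fraction held-out fraction for the map evaluation.
#' @return A list report (serializable with [write_report()]) containing the
#'   dimensions, PCA variance, map test-set R-squared values and the minimum
#'   absolute Jacobian determinant.
#' @export
run_msp_study <- function(n = 6000, fraction = 0.1, n_starts = 1000,
                          base = msp_base_point(), times = seq(2, 20, by = 2),
                          seed = 1,
                          components = c("transient", "optimization", "maps"),
                          test_fraction = 0.3) {
  if (fraction <= 0) abort("fraction must be positive: a degenerate (single-point) ensemble has no dimensionality")
  report <- list(model = "msp", n = n, fraction = fraction, seed = seed)
  ds <- NULL
  if (any(c("transient", "maps") %in% components)) {
    P <- sample_parameters(base, fraction, n, seed = seed)
    ds <- build_transient_dataset(P, "msp", times = times, base = base,
                                  fraction = fraction, seed = seed)
  }
  if ("transient" %in% components) {
    id <- intrinsic_dimension(ds, "output_informed")
    report$transient_dimension <- id$dimension
    report$transient_indices <- id$selection$indices
  }
  if ("optimization" %in% components) {
    opt <- suppressWarnings(
      build_optimization_dataset(base = base, n_starts = n_starts,
                                 times = times, seed = seed + 1L))
    report$n_accepted_fits <- nrow(opt$parameters)
    ratios <- sort(pca_explained(opt$parameters), decreasing = TRUE)
    report$pca_top3 <- sum(ratios[1:3])
    # linear estimate: principal components needed for 99% of the variance
    report$optimization_dimension <- unname(which(cumsum(ratios) >= 0.99)[1])
    ido <- intrinsic_dimension(opt, "parameter_space")
    report$optimization_dimension_dmaps <- ido$dimension
    if (!is.null(report$transient_dimension)) {
      report$dimension_sum <- report$transient_dimension +
        report$optimization_dimension
    }
  }
  if ("maps" %in% components) {
    kap <- t(apply(as_matrix(ds$parameters), 1, function(p) {
      names(p) <- colnames(ds$parameters)
      effective_parameters(p)
    }))
    n_all <- nrow(kap)
    n_test <- round(test_fraction * n_all)
    test <- with_seed(seed + 2L, sample.int(n_all, n_test))
    train_ds <- ensemble_dataset(ds$parameters[-test, ], ds$behaviors[-test, ],
                                 base = base, fraction = fraction,
                                 times = times, observable = "S2")
    id <- intrinsic_dimension(train_ds, "output_informed", n_max = 4000)
    kap_train <- kap[-test, , drop = FALSE][id$rows, , drop = FALSE]
    dd <- double_dmaps_fit(id$model, kap_train,
                           indices = head(id$selection$indices, ncol(kap)),
                           eps_factor = 4)
    pred <- predict(dd, ambient = as_matrix(ds$behaviors)[test, ])
    truth <- kap[test, ]
    r2 <- vapply(seq_len(ncol(truth)), function(j)
      1 - sum((pred[, j] - truth[, j])^2) / sum((truth[, j] - mean(truth[, j]))^2),
      0)
    report$map_test_r2 <- setNames(r2, colnames(kap))
    Phi <- id$model$vectors[, head(id$selection$indices, ncol(kap)) + 1L,
                            drop = FALSE]
    if (ncol(Phi) == ncol(kap)) {
      dets <- jacobian_determinant(function(x) predict(dd, newdata = x), Phi)
      report$min_abs_jacobian <- min(abs(dets))
    }
  }
  report
}

#' End-to-end study of the single-site caricature
#'
#' Samples the caricature ensemble, counts its intrinsic dimension (one
#' effective parameter), optionally trains the conformal autoencoder and
#' reports latent/effective-parameter association and level-set quality.
#'
#' @param n ensemble size (default 2000).
#' @param fraction perturbation half-width (default 0.2).
#' @param base base rates (default [caricature_base_point()], the
#'   `(0.97, 7000, 10000)` regime).
#' @param times observation times (default five points every 2 time units).
#' @param seed master seed.
#' @param run_cae train the conformal autoencoder (default `TRUE`).
#' @param cae_epochs training epochs for the autoencoder.
#' @return A list report: intrinsic dimension, and with `run_cae` the
#'   Spearman correlation between `nu1` and `k_eff`, the orthogonality
#'   score, and the level-set behavior deviation / parameter extent.
#' @export
run_caricature_study <- function(n = 2000, fraction = 0.2,
                                 base = caricature_base_point(),
                                 times = seq(2, 10, by = 2), seed = 1,
                                 run_cae = TRUE, cae_epochs = 500) {
  if (fraction <= 0) abort("fraction must be positive: a degenerate (single-point) ensemble has no dimensionality")
  P <- sample_parameters(base, fraction, n, seed = seed)
  ds <- build_transient_dataset(P, "caricature", times = times,
                                observable = "S1", base = base,
                                fraction = fraction, seed = seed)
  id <- intrinsic_dimension(ds, "output_informed")
  report <- list(model = "caricature", n = n, fraction = fraction,
                 seed = seed, dimension = id$dimension)
  keff <- apply(as_matrix(ds$parameters), 1, function(p) {
    names(p) <- colnames(ds$parameters)
    k_eff(p)
  })
  phi1 <- id$model$vectors[, id$selection$indices[1] + 1L]
  report$phi1_keff_spearman <-
    abs(cor(phi1, keff[round(seq(1, n, length.out = length(phi1)))],
            method = "spearman"))
  if (run_cae) {
    cae <- train_cae(ds, n_eff = 1, epochs = cae_epochs, seed = seed)
    nu <- as_matrix(encode(cae, as_matrix(ds$parameters)))
    report$nu1_keff_spearman <- abs(cor(nu[, 1], keff, method = "spearman"))
    report$orthogonality_score <-
      orthogonality_score(cae, as_matrix(ds$parameters)[seq(1, n, by = 4), ])
    beh_fun <- function(pm) {
      do.call(rbind, lapply(seq_len(nrow(pm)), function(i) {
        p <- pmax(pm[i, ], 1e-8)
        names(p) <- colnames(ds$parameters)
        simulate_caricature(p, times = times)$S1
      }))
    }
    ls <- trace_level_set(cae, grid_n = 10, behavior_fun = beh_fun)
    report$level_set_behavior_deviation <- attr(ls, "max_behavior_deviation")
    report$level_set_parameter_extent <- max(attr(ls, "parameter_extent"))
    report$cae_losses <- cae$report[c("reconstruction_mse", "behavior_mse",
                                      "orthogonality")]
  }
  report
}
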