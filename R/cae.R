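#' Conformal autoencoder for disentangling effective from redundant
#' parameter combinations
#'
#' A Y-shaped architecture of three multilayer perceptrons trained jointly on
#' a parameter/behavior ensemble:
#' \describe{
#'   \item{encoder}{maps a parameter vector to latent coordinates `nu`
#'     (same dimension as the input);}
#'   \item{decoder}{reconstructs the parameter vector from `nu`;}
#'   \item{behavior estimator}{predicts the observed behavior from the first
#'     `n_eff` latent coordinates *only*, so the remaining coordinates are
#'     architecturally unable to influence the predicted behavior.}
#' }
#' The loss is `w1 * reconstruction MSE + w2 * behavior MSE + w3 *
#' orthogonality`, where the orthogonality term is the mean over latent pairs
#' `i != j` of the squared inner product of the input-gradients
#' `<d nu_i / dx, d nu_j / dx>`, averaged over the minibatch and computed
#' with exact reverse-mode differentiation. Driving this term to zero makes
#' the latent coordinates conformal: the effective block parameterizes
#' behavior change, while the redundant block spans the level sets of
#' constant behavior.
#'
#' `n_eff` must be known in advance; it is the intrinsic dimension of the
#' model manifold as counted by [intrinsic_dimension()].
#'
#' Inputs and behaviors are standardized to zero mean / unit variance
#' internally; the orthogonality is measured in standardized input
#' coordinates.
#'
#' @param dataset an [ensemble_dataset()].
#' @param n_eff number of effective latent coordinates (< input dimension).
#' @param hidden hidden-layer widths of each subnetwork (default
#'   `c(32, 32, 32, 32)`, tanh).
#' @param epochs training epochs (default 800).
#' @param batch_size minibatch size (default 256).
#' @param lr initial ADAM learning rate (default 2e-3).
#' @param lr_end final learning rate; when it differs from `lr` the rate
#'   decays geometrically across the epochs. The default keeps the rate
#'   constant, which empirically drives the orthogonality term furthest.
#' @param weights length-3 loss weights `(reconstruction, behavior,
#'   orthogonality)` (default `c(1, 1, 1)`).
#' @param seed RNG seed controlling initialization and batching.
#' @param verbose print loss components every 100 epochs.
#' @return Object of class `cae_model`, including a `report` with the final
#'   loss components and the training seed.
#' @export
train_cae <- function(dataset, n_eff, hidden = c(32, 32, 32, 32),
                      epochs = 800, batch_size = 256, lr = 2e-3,
                      lr_end = lr, weights = c(1, 1, 1), seed = 1,
                      verbose = FALSE) {
  stopifnot(inherits(dataset, "ensemble_dataset"))
  X <- as_matrix(dataset$parameters)
  Y <- as_matrix(dataset$behaviors)
  P <- ncol(X)
  if (n_eff >= P) abort("n_eff must be smaller than the number of parameters")
  if (n_eff < 1) abort("n_eff must be at least 1")
  scx <- col_scaler(X); scy <- col_scaler(Y)
  Xs <- scale_apply(X, scx); Ys <- scale_apply(Y, scy)
  n <- nrow(Xs)
  batch_size <- min(batch_size, n)

  init_net <- function(sizes) {
    lapply(seq_len(length(sizes) - 1L), function(l) {
      list(W = matrix(rnorm(sizes[l] * sizes[l + 1],
                            sd = sqrt(1 / sizes[l])), sizes[l], sizes[l + 1]),
           b = numeric(sizes[l + 1]))
    })
  }
  nets <- with_seed(seed, list(
    enc = init_net(c(P, hidden, P)),
    dec = init_net(c(P, hidden, P)),
    beh = init_net(c(n_eff, hidden, ncol(Ys)))
  ))

  # ADAM state mirrors the nets structure
  mm <- lapply(nets, function(net) lapply(net, function(l)
    list(W = l$W * 0, b = l$b * 0)))
  vv <- mm
  beta1 <- 0.9; beta2 <- 0.999; epsadam <- 1e-8

  # forward pass of one subnet on the tape; returns output node and the
  # tanh-activation nodes needed for the input-gradient sweep
  net_forward <- function(tape, net_nodes, x_node) {
    a <- x_node
    acts <- list()
    L <- length(net_nodes)
    for (l in seq_len(L)) {
      z <- tp_add_bias(tp_matmul(a, net_nodes[[l]]$W, tape), net_nodes[[l]]$b,
                       tape)
      if (l < L) {
        a <- tp_tanh(z, tape)
        acts[[l]] <- a
      } else a <- z
    }
    list(out = a, acts = acts)
  }

  mse_node <- function(tape, a, b) tp_mean_all(tp_square(tp_sub(a, b, tape),
                                                         tape), tape)

  pair_idx <- which(upper.tri(diag(P)), arr.ind = TRUE)
  step <- 0L
  history <- NULL
  batches_per_epoch <- max(1L, n %/% batch_size)
  run <- with_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      lr_ep <- lr * (lr_end / lr)^((ep - 1) / max(1, epochs - 1))
      perm <- sample.int(n)
      for (bt in seq_len(batches_per_epoch)) {
        rows <- perm[((bt - 1L) * batch_size + 1L):min(bt * batch_size, n)]
        B <- length(rows)
        tape <- tape_new()
        node_nets <- lapply(nets, function(net) lapply(net, function(l)
          list(W = tp_param(tape, l$W), b = tp_param(tape, l$b))))
        xb <- tp_const(tape, Xs[rows, , drop = FALSE])
        yb <- tp_const(tape, Ys[rows, , drop = FALSE])
        enc <- net_forward(tape, node_nets$enc, xb)
        nu <- enc$out
        dec <- net_forward(tape, node_nets$dec, nu)
        recon <- mse_node(tape, dec$out, xb)
        beh <- net_forward(tape, node_nets$beh, tp_cols(nu, seq_len(n_eff), tape))
        behl <- mse_node(tape, beh$out, yb)
        # exact input-gradients of each latent coordinate via reverse sweep
        L <- length(node_nets$enc)
        grads <- lapply(seq_len(P), function(i) {
          G <- tp_row_broadcast(node_nets$enc[[L]]$W, i, B, tape)
          for (l in (L - 1L):1L) {
            G <- tp_mul(G, tp_one_minus_sq(enc$acts[[l]], tape), tape)
            G <- tp_matmul(G, node_nets$enc[[l]]$W, tape, tb = TRUE)
          }
          G
        })
        ortho <- NULL
        for (r in seq_len(nrow(pair_idx))) {
          s <- tp_rowsum(tp_mul(grads[[pair_idx[r, 1]]],
                                grads[[pair_idx[r, 2]]], tape), tape)
          term <- tp_mean_all(tp_square(s, tape), tape)
          ortho <- if (is.null(ortho)) term else tp_add(ortho, term, tape)
        }
        ortho <- tp_scale(ortho, 1 / nrow(pair_idx), tape)
        loss <- tp_add(tp_add(tp_scale(recon, weights[1], tape),
                              tp_scale(behl, weights[2], tape), tape),
                       tp_scale(ortho, weights[3], tape), tape)
        tp_backward(tape, loss)
        # ADAM update
        step <- step + 1L
        for (nm in names(nets)) {
          for (l in seq_along(nets[[nm]])) {
            for (slot in c("W", "b")) {
              g <- node_nets[[nm]][[l]][[slot]]$grad
              if (is.null(g)) g <- nets[[nm]][[l]][[slot]] * 0
              if (slot == "b") g <- as.numeric(g)
              mm[[nm]][[l]][[slot]] <- beta1 * mm[[nm]][[l]][[slot]] +
                (1 - beta1) * g
              vv[[nm]][[l]][[slot]] <- beta2 * vv[[nm]][[l]][[slot]] +
                (1 - beta2) * g^2
              upd <- lr_ep * (mm[[nm]][[l]][[slot]] / (1 - beta1^step)) /
                (sqrt(vv[[nm]][[l]][[slot]] / (1 - beta2^step)) + epsadam)
              nets[[nm]][[l]][[slot]] <- nets[[nm]][[l]][[slot]] - upd
            }
          }
        }
        if (!is.finite(loss$value[1])) {
          abort(sprintf("non-finite loss at epoch %d (recon %.3g, behavior %.3g, orthogonality %.3g); try a smaller learning rate",
                        ep, recon$value[1], behl$value[1], ortho$value[1]))
        }
      }
      if (ep %% 25 == 0 || ep == epochs) {
        history <- rbind(history,
                         c(epoch = ep, recon = recon$value[1],
                           behavior = behl$value[1], ortho = ortho$value[1]))
      }
      if (verbose && ep %% 100 == 0) {
        message(sprintf("epoch %4d  recon %.3e  behavior %.3e  ortho %.3e",
                        ep, recon$value[1], behl$value[1], ortho$value[1]))
      }
    }
    list(nets = nets, history = history)
  })

  model <- structure(
    list(nets = run$nets, n_eff = n_eff, scx = scx, scy = scy,
         hidden = hidden, seed = seed, weights = weights,
         par_names = colnames(X),
         history = as_tibble(as.data.frame(run$history))),
    class = "cae_model")
  model$latents <- as_matrix(encode(model, X))
  final <- utils::tail(run$history, 1)
  model$report <- list(reconstruction_mse = unname(final[1, "recon"]),
                       behavior_mse = unname(final[1, "behavior"]),
                       orthogonality = unname(final[1, "ortho"]),
                       seed = seed, epochs = epochs,
                       batch_size = batch_size, weights = weights)
  model
}

net_eval <- function(net, A, keep_acts = FALSE) {
  L <- length(net)
  acts <- list()
  for (l in seq_len(L)) {
    A <- sweep(A %*% net[[l]]$W, 2, net[[l]]$b, "+")
    if (l < L) {
      A <- tanh(A)
      if (keep_acts) acts[[l]] <- A
    }
  }
  if (keep_acts) list(out = A, acts = acts) else A
}

#' Encode parameters to conformal latent coordinates
#'
#' @param model a trained [train_cae()] model.
#' @param p matrix / data frame / named vector of parameter vectors.
#' @return Tibble of latent coordinates `nu1, nu2, ...`; the first
#'   `model$n_eff` columns are the effective block.
#' @export
encode <- function(model, p) {
  stopifnot(inherits(model, "cae_model"))
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  nu <- net_eval(model$nets$enc, scale_apply(p, model$scx))
  colnames(nu) <- paste0("nu", seq_len(ncol(nu)))
  as_tibble(as.data.frame(nu))
}

#' Decode latent coordinates back to parameter vectors
#'
#' Latent coordinates outside the range observed on the training data are
#' flagged with an extrapolation warning.
#'
#' @param model a trained [train_cae()] model.
#' @param nu matrix / data frame of latent coordinates.
#' @return Tibble of reconstructed parameter vectors.
#' @export
decode <- function(model, nu) {
  stopifnot(inherits(model, "cae_model"))
  if (is.null(dim(nu))) nu <- matrix(nu, nrow = 1)
  nu <- as_matrix(nu)
  rng <- apply(model$latents, 2, range)
  out_of_range <- sweep(nu, 2, rng[1, ], "<") | sweep(nu, 2, rng[2, ], ">")
  if (any(out_of_range)) {
    warn(sprintf("%d latent value(s) outside the training range; decoded parameters are extrapolations",
                 sum(out_of_range)))
  }
  ps <- net_eval(model$nets$dec, nu)
  ps <- scale_invert(ps, model$scx)
  colnames(ps) <- model$par_names
  as_tibble(as.data.frame(ps))
}

#' Predict behavior from the effective latent block
#'
#' Evaluates the behavior-estimator subnetwork; only the first `n_eff`
#' latent coordinates enter, by construction.
#'
#' @param model a trained [train_cae()] model.
#' @param nu_eff matrix (or vector) of effective latent coordinates.
#' @return Tibble of predicted behaviors.
#' @export
cae_predict_behavior <- function(model, nu_eff) {
  stopifnot(inherits(model, "cae_model"))
  if (is.null(dim(nu_eff))) nu_eff <- matrix(nu_eff, ncol = model$n_eff)
  B <- net_eval(model$nets$beh, as_matrix(nu_eff))
  as_tibble(as.data.frame(scale_invert(B, model$scy)))
}

# exact input-gradients (standardized coordinates) of all latent coordinates;
# returns a list of n x P matrices, one per latent coordinate
encoder_input_gradients <- function(model, p) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  Xs <- scale_apply(p, model$scx)
  net <- model$nets$enc
  L <- length(net)
  fw <- net_eval(net, Xs, keep_acts = TRUE)
  n <- nrow(Xs)
  P <- ncol(net[[L]]$W)
  lapply(seq_len(P), function(i) {
    G <- matrix(net[[L]]$W[, i], n, nrow(net[[L]]$W), byrow = TRUE)
    for (l in (L - 1L):1L) {
      G <- (G * (1 - fw$acts[[l]]^2)) %*% t(net[[l]]$W)
    }
    G
  })
}

#' Gradient-orthogonality score of the latent coordinates
#'
#' Mean absolute cosine of the angle between the input-gradients of every
#' latent pair, averaged over the supplied points: 0 for perfectly conformal
#' coordinates. Models with a single latent coordinate return 0 by
#' convention.
#'
#' @param model a trained [train_cae()] model.
#' @param points matrix / data frame of parameter vectors (default: the
#'   training latents' preimages are not stored, so pass the data of
#'   interest).
#' @return Scalar score in `[0, 1]`.
#' @export
orthogonality_score <- function(model, points) {
  stopifnot(inherits(model, "cae_model"))
  G <- encoder_input_gradients(model, points)
  P <- length(G)
  if (P < 2) return(0)
  pairs <- which(upper.tri(diag(P)), arr.ind = TRUE)
  total <- 0
  for (r in seq_len(nrow(pairs))) {
    gi <- G[[pairs[r, 1]]]; gj <- G[[pairs[r, 2]]]
    num <- abs(rowSums(gi * gj))
    den <- sqrt(rowSums(gi^2) * rowSums(gj^2))
    total <- total + mean(num / pmax(den, .Machine$double.eps))
  }
  total / nrow(pairs)
}

#' Trace a level set of constant behavior in full parameter space
#'
#' Fixes the effective latent block and sweeps a grid over the observed range
#' of the redundant block; each grid point is decoded to a parameter vector
#' and (optionally) simulated, quantifying how little the behavior changes
#' while the parameters move. This reconstructs, point by point, the level
#' set of original parameters consistent with one observed behavior.
#'
#' @param model a trained [train_cae()] model.
#' @param nu_eff_fixed value(s) of the effective latent block (default: the
#'   componentwise median of the training latents). Values at or beyond the
#'   training extremes trigger a clipping warning.
#' @param grid_n grid resolution per redundant coordinate (default 20).
#' @param behavior_fun optional function `parameter matrix -> behavior
#'   matrix` used to verify level-set quality by forward simulation.
#' @param range_quantiles quantile window of the redundant block to sweep
#'   (default `c(0.05, 0.95)`).
#' @return Tibble with latent coordinates, decoded parameters, and (when
#'   `behavior_fun` is given) the relative behavior deviation from the grid
#'   center; attributes `max_behavior_deviation` and `parameter_extent`
#'   summarize level-set quality.
#' @export
trace_level_set <- function(model, nu_eff_fixed = NULL, grid_n = 20,
                            behavior_fun = NULL,
                            range_quantiles = c(0.05, 0.95)) {
  stopifnot(inherits(model, "cae_model"))
  P <- ncol(model$latents)
  n_eff <- model$n_eff
  red_idx <- (n_eff + 1L):P
  lat <- model$latents
  if (is.null(nu_eff_fixed)) {
    nu_eff_fixed <- apply(lat[, seq_len(n_eff), drop = FALSE], 2, median)
  }
  eff_rng <- apply(lat[, seq_len(n_eff), drop = FALSE], 2, range)
  if (any(nu_eff_fixed <= eff_rng[1, ] | nu_eff_fixed >= eff_rng[2, ])) {
    warn("effective latent value at or beyond the sampled extremes; the level set is clipped to the sampled region")
  }
  qs <- apply(lat[, red_idx, drop = FALSE], 2, quantile,
              probs = range_quantiles)
  axes <- lapply(seq_along(red_idx), function(j) {
    if (grid_n == 1) mean(qs[, j]) else seq(qs[1, j], qs[2, j],
                                            length.out = grid_n)
  })
  grid <- as.matrix(expand.grid(axes))
  nu <- matrix(0, nrow(grid), P)
  nu[, seq_len(n_eff)] <- matrix(nu_eff_fixed, nrow(grid), n_eff, byrow = TRUE)
  nu[, red_idx] <- grid
  pars <- suppressWarnings(decode(model, nu))
  out <- as_tibble(as.data.frame(nu))
  names(out) <- paste0("nu", seq_len(P))
  out <- dplyr::bind_cols(out, pars)
  extent <- apply(as_matrix(pars), 2, function(col)
    diff(range(col)) / max(abs(mean(col)), .Machine$double.eps))
  max_dev <- NA_real_
  if (!is.null(behavior_fun)) {
    B <- behavior_fun(as_matrix(pars))
    center <- B[which.min(rowSums(sweep(grid, 2, colMeans(grid))^2)), ]
    dev <- apply(B, 1, function(bi) max(abs(bi - center) / pmax(abs(center),
                                                                .Machine$double.eps)))
    out$behavior_deviation <- dev
    max_dev <- max(dev)
  }
  attr(out, "max_behavior_deviation") <- max_dev
  attr(out, "parameter_extent") <- extent
  out
}

#' Estimate the effective latent coordinate from new behavior
#'
#' The Double DMaps route from observations to the conformal effective
#' coordinate: an output-informed diffusion map of the training behaviors
#' carries a geometric-harmonics interpolant of the encoder's first latent
#' coordinate; a new behavior is projected by Nystrom extension and the
#' latent value read off. Behaviors far from the sampled manifold are
#' rejected.
#'
#' @param model a trained [train_cae()] model.
#' @param dataset the training [ensemble_dataset()].
#' @param behavior_new matrix or vector of new behavior observations.
#' @param n_max subsample cap for the diffusion map (default 2000).
#' @return Numeric vector of estimated `nu1` values.
#' @export
estimate_nu1_from_behavior <- function(model, dataset, behavior_new,
                                       n_max = 2000) {
  stopifnot(inherits(model, "cae_model"), inherits(dataset, "ensemble_dataset"))
  B <- as_matrix(dataset$behaviors)
  nu1 <- as_matrix(encode(model, as_matrix(dataset$parameters)))[, 1]
  n <- nrow(B)
  idx <- if (n > n_max) round(seq(1, n, length.out = n_max)) else seq_len(n)
  dm <- dmaps_fit(B[idx, , drop = FALSE], m = 10)
  dd <- double_dmaps_fit(dm, nu1[idx])
  if (is.null(dim(behavior_new))) behavior_new <- matrix(behavior_new, nrow = 1)
  nearest <- apply(sq_dist(as_matrix(behavior_new), dm$X), 1, min)
  if (any(nearest > 9 * dm$epsilon)) {
    abort("behavior lies off the sampled model manifold")
  }
  as.numeric(predict(dd, ambient = behavior_new))
}

#' @export
print.cae_model <- function(x, ...) {
  cat(sprintf("<cae_model> %d -> %d latent (%d effective), hidden [%s]\n",
              length(x$par_names), ncol(x$latents), x$n_eff,
              paste(x$hidden, collapse = ", ")))
  cat(sprintf("  final losses: recon %.3e, behavior %.3e, orthogonality %.3e\n",
              x$report$reconstruction_mse, x$report$behavior_mse,
              x$report$orthogonality))
  invisible(x)
}
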