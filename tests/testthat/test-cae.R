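toy_cae <- function() {
  fixture("toy_cae", function() {
    toy <- toy_fig1_dataset(2000, seed = 5)
    ds <- ensemble_dataset(toy[, c("p1", "p2")], toy[, "f", drop = FALSE],
                           observable = "f")
    list(toy = toy, ds = ds,
         model = train_cae(ds, n_eff = 1, epochs = 1200, seed = 1))
  })
}

test_that("conformal autoencoder disentangles the analytic toy into its
           effective and redundant combinations", {
  tc <- toy_cae()
  X <- as.matrix(tc$toy[, c("p1", "p2")])
  nu <- as.matrix(encode(tc$model, X))
  # nu1 is one-to-one with the effective combination p1 p2
  expect_gt(abs(cor(nu[, 1], tc$toy$phi, method = "spearman")), 0.99)
  # nu2 is one-to-one with the redundant combination p1^2 - p2^2
  expect_gt(abs(cor(nu[, 2], tc$toy$psi, method = "spearman")), 0.99)
  # latent gradients are near-orthogonal over the sampled square
  expect_lte(orthogonality_score(tc$model, X), 0.05)
})

test_that("dropping the orthogonality penalty degrades conformality", {
  tc <- toy_cae()
  ab <- train_cae(tc$ds, n_eff = 1, epochs = 250, weights = c(1, 1, 0),
                  seed = 1)
  X <- as.matrix(tc$toy[, c("p1", "p2")])
  expect_gt(orthogonality_score(ab, X),
            2 * orthogonality_score(tc$model, X))
})

test_that("encode/decode round-trips within the reconstruction tolerance", {
  tc <- toy_cae()
  X <- as.matrix(tc$toy[, c("p1", "p2")])
  held <- seq(1, nrow(X), by = 7)
  nu <- as.matrix(encode(tc$model, X[held, ]))
  back <- as.matrix(decode(tc$model, nu))
  expect_lt(sqrt(mean((back - X[held, ])^2)) / sqrt(mean(X[held, ]^2)), 0.01)
  # deterministic encoding
  expect_identical(encode(tc$model, X[1:5, ]), encode(tc$model, X[1:5, ]))
  # out-of-range latents are flagged
  rng <- apply(tc$model$latents, 2, range)
  expect_warning(decode(tc$model, rng[2, ] + 10 * (rng[2, ] - rng[1, ])),
                 "extrapolation")
})

test_that("the behavior estimator is blind to the redundant block", {
  tc <- toy_cae()
  nu <- as.matrix(encode(tc$model, as.matrix(tc$toy[1:20, c("p1", "p2")])))
  b1 <- cae_predict_behavior(tc$model, nu[, 1])
  # by architecture only the effective block enters; shifting nu2 cannot
  # change the prediction because it never reaches the subnetwork
  expect_identical(b1, cae_predict_behavior(tc$model, nu[, 1, drop = FALSE]))
  pred <- as.matrix(b1)
  expect_lt(max(abs(pred - tc$toy$f[1:20])), 0.05)
})

test_that("orthogonality score conventions", {
  tc <- toy_cae()
  # single-latent model: no pairs, score 0 by convention
  single <- tc$model
  single$nets$enc[[length(single$nets$enc)]]$W <-
    single$nets$enc[[length(single$nets$enc)]]$W[, 1, drop = FALSE]
  single$nets$enc[[length(single$nets$enc)]]$b <-
    single$nets$enc[[length(single$nets$enc)]]$b[1]
  expect_equal(orthogonality_score(single,
                                   as.matrix(tc$toy[1:10, c("p1", "p2")])), 0)
  expect_error(train_cae(tc$ds, n_eff = 2), "smaller")
})

test_that("level-set tracing holds behavior fixed while parameters move", {
  ds <- caricature_ensemble(n = 1500, seed = 3)
  model <- fixture("car_cae", function()
    train_cae(ds, n_eff = 1, epochs = 500, seed = 1))
  keff <- keff_of(ds$parameters)
  nu <- as.matrix(encode(model, as.matrix(ds$parameters)))
  expect_gt(abs(cor(nu[, 1], keff, method = "spearman")), 0.99)
  beh_fun <- function(pm) {
    do.call(rbind, lapply(seq_len(nrow(pm)), function(i) {
      p <- pmax(pm[i, ], 1e-8)
      names(p) <- colnames(ds$parameters)
      simulate_caricature(p, times = seq(2, 10, 2))$S1
    }))
  }
  ls <- trace_level_set(model, grid_n = 8, behavior_fun = beh_fun)
  # behavior stays within 1 percent across the traced level set while at
  # least one parameter sweeps over 10 percent
  expect_lte(attr(ls, "max_behavior_deviation"), 0.01)
  expect_gte(max(attr(ls, "parameter_extent")), 0.10)
  # a single grid point has nothing to deviate from
  ls1 <- trace_level_set(model, grid_n = 1, behavior_fun = beh_fun)
  expect_equal(attr(ls1, "max_behavior_deviation"), 0)
  # fixing the effective coordinate at the sampled extreme clips the set
  expect_warning(trace_level_set(model, nu_eff_fixed = max(model$latents[, 1]),
                                 grid_n = 2),
                 "clipped")
})

test_that("redundant-direction moves change behavior far less than
           effective-direction moves", {
  ds <- caricature_ensemble(n = 1500, seed = 3)
  model <- fixture("car_cae", function()
    train_cae(ds, n_eff = 1, epochs = 500, seed = 1))
  lat <- model$latents
  med <- apply(lat, 2, median)
  step <- apply(lat, 2, function(col) 0.25 * diff(quantile(col, c(0.25, 0.75))))
  beh_of <- function(nu) {
    p <- pmax(as.matrix(suppressWarnings(decode(model, nu))), 1e-8)
    colnames(p) <- model$par_names
    pp <- p[1, ]; names(pp) <- model$par_names
    simulate_caricature(pp, times = seq(2, 10, 2))$S1
  }
  b0 <- beh_of(matrix(med, 1))
  dev <- function(j) {
    nu <- med; nu[j] <- nu[j] + step[j]
    max(abs(beh_of(matrix(nu, 1)) - b0) / b0)
  }
  expect_gt(dev(1), 10 * max(dev(2), dev(3)))
})

test_that("the effective coordinate is recoverable from new behavior through
           the Double DMaps route", {
  ds <- caricature_ensemble(n = 1500, seed = 3)
  model <- fixture("car_cae", function()
    train_cae(ds, n_eff = 1, epochs = 500, seed = 1))
  nu1 <- as.matrix(encode(model, as.matrix(ds$parameters)))[, 1]
  members <- c(10, 500, 1200)
  est <- estimate_nu1_from_behavior(model, ds,
                                    as.matrix(ds$behaviors)[members, ])
  span <- diff(range(nu1))
  expect_lt(max(abs(est - nu1[members])) / span, 0.02)
  # two parameter settings with matching behavior give matching nu1
  B <- as.matrix(ds$behaviors)
  d2 <- colSums((t(B) - B[members[1], ])^2)
  d2[members[1]] <- Inf
  i2 <- which.min(d2)
  pair_est <- estimate_nu1_from_behavior(model, ds, B[c(members[1], i2), ])
  expect_lt(abs(diff(pair_est)) / span, 0.02)
  expect_error(estimate_nu1_from_behavior(model, ds, rep(0, 5)), "manifold")
})
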