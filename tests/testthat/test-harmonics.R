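test_that("geometric harmonics reproduce constants and training projections", {
  set.seed(1)
  X <- matrix(runif(200), 100, 2)
  fit <- gh_fit(X, rep(3.5, 100))
  expect_equal(as.numeric(predict(fit, matrix(runif(20), 10, 2))),
               rep(3.5, 10), tolerance = 1e-2)
  expect_equal(as.numeric(predict(fit, X)), rep(3.5, 100), tolerance = 1e-3)
  # training-point evaluation returns the projected values
  y <- sin(2 * X[, 1]) + X[, 2]^2
  fit2 <- gh_fit(X, y)
  proj <- fit2$psi %*% fit2$coef
  expect_equal(as.numeric(predict(fit2, X)), as.numeric(proj),
               tolerance = 1e-6)
  expect_error(gh_fit(X, y, delta = 1), "retained")
})

test_that("geometric harmonics interpolate a smooth 1D function accurately", {
  x <- seq(0, 1, length.out = 200)
  y <- sin(2 * pi * x)
  fit <- gh_fit(cbind(x), y)
  mids <- (x[-1] + x[-200]) / 2
  expect_lt(max(abs(predict(fit, cbind(mids)) - sin(2 * pi * mids))), 1e-3)
})

test_that("geometric harmonics fitting is a projection (idempotent)", {
  set.seed(2)
  X <- matrix(runif(160), 80, 2)
  y <- cos(X[, 1]) * X[, 2]
  fit <- gh_fit(X, y)
  smoothed <- as.numeric(predict(fit, X))
  fit2 <- gh_fit(X, smoothed, epsilon = fit$epsilon, delta = fit$delta)
  expect_equal(fit2$coef, fit$coef, tolerance = 1e-6)
})

test_that("double dmaps reproduce their own coordinates and compose with
           Nystrom for out-of-sample prediction", {
  set.seed(3)
  X <- cbind(runif(400, 0, 2), runif(400, 0, 2))
  dm <- dmaps_fit(X, m = 6)
  phi1 <- dm$vectors[, 2]
  dd <- double_dmaps_fit(dm, phi1, indices = c(1, 2))
  # training-point evaluation returns the projection onto the retained span
  proj <- as.numeric(dd$gh$psi %*% dd$gh$coef)
  expect_equal(as.numeric(predict(dd, newdata = dm$vectors[, 2:3])), proj,
               tolerance = 1e-6)
  expect_equal(proj, phi1, tolerance = 1e-3)
  # out-of-sample through the ambient route
  Xn <- cbind(runif(50, 0.2, 1.8), runif(50, 0.2, 1.8))
  pred <- predict(dd, ambient = Xn)
  truth <- nystrom_extend(dm, Xn)[, 2]
  expect_equal(as.numeric(pred), truth, tolerance = 1e-4)
})

test_that("effective parameters are recoverable from diffusion coordinates
           with near-perfect test-set fidelity", {
  ds <- msp_ensemble(n = 2000, seed = 11)
  kap <- kappa_of(ds$parameters)
  id <- intrinsic_dimension(ds, n_max = 1500)
  rows <- id$rows
  dd <- double_dmaps_fit(id$model, kap[rows, ],
                         indices = head(id$selection$indices, 3),
                         eps_factor = 4)
  # held-out rows, mapped through Nystrom
  held <- setdiff(seq_len(nrow(kap)), rows)[1:300]
  pred <- predict(dd, ambient = as.matrix(ds$behaviors)[held, ])
  for (j in 1:3) {
    r2 <- 1 - sum((pred[, j] - kap[held, j])^2) /
      sum((kap[held, j] - mean(kap[held, j]))^2)
    expect_gt(r2, 0.99)
  }
})

test_that("jacobian determinants recover linear maps and certify the
           data-driven coordinate change", {
  set.seed(4)
  pts <- matrix(runif(60), 20, 3)
  expect_equal(jacobian_determinant(function(x) x, pts), rep(1, 20))
  A <- matrix(c(2, 0.5, 0, 1, 3, 0, 0, 1, 1), 3, 3)
  expect_equal(jacobian_determinant(function(x) x %*% A, pts),
               rep(det(t(A)), 20), tolerance = 1e-6)
  expect_error(jacobian_determinant(function(x) x[, 1:2], pts), "square")
})

test_that("behavior prediction from effective parameters is accurate and
           guards its domain", {
  ds <- fixture("kappa1500", function() sample_kappa_dataset(n = 1500, seed = 31))
  train <- ensemble_dataset(ds$parameters[1:1200, ], ds$behaviors[1:1200, ],
                            times = seq(2, 20, 2), observable = "S2")
  map <- fixture("kmap1500", function() fit_behavior_map(train))
  test <- 1201:1500
  pred <- as.matrix(predict_behavior(map, ds$parameters[test, ]))
  truth <- as.matrix(ds$behaviors)[test, ]
  expect_lt(max(abs(pred - truth) / truth), 0.01)
  # nominal triplet reproduces the reduced-model reference transient closely
  pnom <- as.numeric(predict_behavior(map, kappa_nominal()))
  ref <- simulate_reduced(kappa_nominal(), times = seq(2, 20, 2))$S2
  expect_lt(max(abs(pnom - ref) / ref), 1e-3)
  w <- capture_warnings(predict_behavior(map, c(kappa1 = 1.5, kappa2 = 0.232,
                                                pi = 0.362)))
  expect_true(any(grepl("extrapolation", w)))
})

test_that("effective parameters are estimated from unseen behaviors and the
           directed maps are mutually consistent", {
  ds <- fixture("kappa1500", function() sample_kappa_dataset(n = 1500, seed = 31))
  train <- ensemble_dataset(ds$parameters[1:1200, ], ds$behaviors[1:1200, ],
                            times = seq(2, 20, 2), observable = "S2")
  map <- fixture("kmap1500", function() fit_behavior_map(train))
  test <- 1201:1500
  est <- as.matrix(estimate_effective_parameters(map, ds$behaviors[test, ]))
  truth <- as.matrix(ds$parameters)[test, ]
  rel <- rowMeans(abs(est - truth) / truth)
  # typical held-out member recovered within 1 percent
  expect_lt(median(rel), 0.01)
  # round trip estimate -> predict returns the observed behavior (2x the
  # single-map tolerances, checked at the 95th percentile)
  back <- suppressWarnings(as.matrix(predict_behavior(map, est)))
  rt <- abs(back - as.matrix(ds$behaviors)[test, ]) /
    as.matrix(ds$behaviors)[test, ]
  expect_lt(quantile(rt, 0.95), 0.02)
  # behavior of the full model at the base point: kappa1 recovered at the
  # nominal 0.467 (1 percent at this training size)
  kh <- as.matrix(estimate_effective_parameters(
    map, simulate_msp(msp_base_point())$S2))
  expect_lt(abs(kh[1, 1] - 0.467) / 0.467, 0.01)
  # a flat behavior vector lies off the model manifold
  expect_error(estimate_effective_parameters(map, rep(0, 10)), "manifold")
})
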