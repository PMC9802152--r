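test_that("diffusion map structure: trivial eigenpair, ordering, determinism", {
  set.seed(2)
  X <- cbind(runif(300), runif(300))
  dm <- dmaps_fit(X, m = 8)
  expect_equal(dm$eigenvalues[1], 1, tolerance = 1e-10)
  expect_equal(dm$vectors[, 1], rep(1, 300), tolerance = 1e-8)
  expect_true(all(diff(dm$eigenvalues) <= 1e-12))
  expect_true(all(abs(dm$eigenvalues) <= 1 + 1e-10))
  # deterministic including signs
  dm2 <- dmaps_fit(X, m = 8)
  expect_identical(dm$vectors, dm2$vectors)
  # row-stochasticity of the normalized kernel
  W <- exp(-as.matrix(dist(X))^2 / dm$epsilon)
  q <- rowSums(W)
  W <- W / outer(q, q)
  P <- W / rowSums(W)
  expect_equal(unname(rowSums(P)), rep(1, 300), tolerance = 1e-12)
  expect_error(dmaps_fit(X * 1e6, epsilon = 1e-12), "diagonal")
})

test_that("circle data embeds into a cos/sin pair", {
  set.seed(1)
  theta <- runif(400, 0, 2 * pi)
  dm <- dmaps_fit(cbind(cos(theta), sin(theta)), m = 10)
  sel <- parsimonious_select(dm)
  # a closed 1-manifold needs two embedding coordinates; both are retained
  # because neither is a function of the other
  expect_identical(sel$indices, c(1L, 2L))
  # (phi1, phi2) is the (cos, sin) pair up to rotation: angles reproduce the
  # circle parameterization
  ang <- atan2(dm$vectors[, 3], dm$vectors[, 2])
  r <- sqrt(dm$vectors[, 2]^2 + dm$vectors[, 3]^2)
  expect_lt(sd(r) / mean(r), 0.1)
  expect_gt(abs(cor(sin(ang), sin(theta))) + abs(cor(sin(ang), cos(theta))), 0.99)
})

test_that("anisotropic strip: long axis first, short axis at a higher index", {
  set.seed(3)
  X <- cbind(runif(800, 0, 5), runif(800, 0, 1))
  dm <- dmaps_fit(X, m = 12)
  sel <- parsimonious_select(dm)
  expect_gt(abs(cor(dm$vectors[, 2], X[, 1])), 0.95)
  # the short-axis direction surfaces at a higher index and is retained
  short <- sel$indices[vapply(sel$indices, function(k)
    abs(cor(dm$vectors[, k + 1], X[, 2])) > 0.9, TRUE)]
  expect_gte(length(short), 1)
  expect_gt(min(short), 1)
})

test_that("duplicated points get duplicated eigenvector entries", {
  set.seed(4)
  X <- cbind(runif(80), runif(80))
  X2 <- rbind(X, X[1:5, ])
  dm <- dmaps_fit(X2, m = 5)
  expect_equal(dm$vectors[81:85, ], dm$vectors[1:5, ], tolerance = 1e-8)
})

test_that("row permutation permutes eigenvectors identically", {
  set.seed(5)
  X <- cbind(runif(150), runif(150) * 0.3)
  perm <- sample.int(150)
  dm1 <- dmaps_fit(X, m = 4)
  dm2 <- dmaps_fit(X[perm, ], m = 4)
  # compare up to sign (the sign convention follows the first large entry,
  # which moves under permutation)
  for (j in 2:5) {
    a <- dm1$vectors[perm, j]; b <- dm2$vectors[, j]
    expect_equal(abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2)), 1,
                 tolerance = 1e-6)
  }
})

test_that("kernel-scale rules behave and agree within a small factor", {
  D <- matrix(2, 5, 5); diag(D) <- 0
  expect_equal(choose_epsilon(D), 4)
  set.seed(6)
  X <- matrix(rnorm(400), 200, 2)
  d <- dist(X)
  expect_equal(choose_epsilon(as.matrix(d) * 3), 9 * choose_epsilon(as.matrix(d)))
  r_med <- choose_epsilon(d)
  r_pla <- choose_epsilon(d, rule = "plateau")
  expect_lt(max(r_med / r_pla, r_pla / r_med), 3)
})

test_that("harmonics are rejected by the parsimonious residual", {
  set.seed(7)
  x <- sort(runif(400, -1, 1))
  Phi <- cbind(x, x^2 - mean(x^2), runif(400, -1, 1))
  sel <- parsimonious_select(Phi, max_points = 400)
  expect_lt(sel$residuals[2], 0.2)   # exact harmonic of phi1: dropped
  expect_gt(sel$residuals[3], 0.8)   # independent noise: genuinely new
  expect_true(1 %in% sel$indices)
  expect_false(2 %in% sel$indices)
  expect_error(parsimonious_select(Phi, threshold = 1.2), "threshold")
})

test_that("Nystrom extension reproduces training points and interpolates", {
  set.seed(8)
  x <- sort(runif(300, 0, 1))
  dm <- dmaps_fit(cbind(x), m = 5)
  ext <- nystrom_extend(dm, cbind(x[10:20]))
  expect_equal(ext, dm$vectors[10:20, ], tolerance = 1e-8)
  # midpoints of a dense 1D set extend between their neighbors' values
  mids <- (x[-1] + x[-length(x)]) / 2
  extm <- nystrom_extend(dm, cbind(mids))
  lo <- pmin(dm$vectors[-1, 2], dm$vectors[-length(x), 2]) - 1e-6
  hi <- pmax(dm$vectors[-1, 2], dm$vectors[-length(x), 2]) + 1e-6
  inside <- mean(extm[, 2] >= lo & extm[, 2] <= hi)
  expect_gt(inside, 0.95)
  expect_warning(nystrom_extend(dm, cbind(50)), "extrapolation")
})

test_that("caricature ensemble is intrinsically one-dimensional", {
  ds <- caricature_ensemble(n = 1000, seed = 13)
  id <- intrinsic_dimension(ds, "output_informed")
  expect_equal(id$dimension, 1)
  keff <- keff_of(ds$parameters)[id$rows]
  phi1 <- id$model$vectors[, 2]
  expect_gt(abs(cor(phi1, keff, method = "spearman")), 0.99)
})

test_that("dimension counts are stable across a tenfold kernel-scale sweep", {
  ds <- caricature_ensemble(n = 1000, seed = 13)
  B <- as.matrix(ds$behaviors)
  eps0 <- 0.5 * max(as.matrix(dist(B))^2)
  d1 <- intrinsic_dimension(ds, epsilon = eps0)$dimension
  d2 <- intrinsic_dimension(ds, epsilon = 10 * eps0)$dimension
  expect_equal(d1, d2)
})

test_that("PCA explained-variance ratios behave on known inputs", {
  u <- runif(50); v <- runif(4)
  expect_equal(pca_explained(outer(u, v)), c(1, 0, 0, 0), tolerance = 1e-12)
  set.seed(9)
  G <- matrix(rnorm(4000), 1000, 4)
  expect_true(all(abs(pca_explained(G) - 0.25) < 0.05))
})
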