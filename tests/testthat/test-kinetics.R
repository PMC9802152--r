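test_that("mass-action right-hand side respects stoichiometry and conservation", {
  p <- msp_base_point()
  s0 <- msp_initial_state()
  d <- msp_rhs(s0, p)
  # no complex present: no product formation, binding at mass-action rate
  expect_equal(unname(d[["S2"]]), 0)
  expect_equal(unname(d[["ES0"]]), p[["kf1"]] * 0.66 * 5)
  # exact conservation of enzyme and substrate for random states
  set.seed(1)
  for (i in 1:20) {
    s <- setNames(runif(6, 0, 5), names(s0))
    dv <- msp_rhs(s, p)
    expect_equal(unname(dv[["E"]] + dv[["ES0"]] + dv[["ES1"]]), 0)
    expect_equal(unname(sum(dv[c("S0", "S1", "S2", "ES0", "ES1")])), 0)
  }
  expect_error(msp_rhs(s0, replace(p, 1, -1)), "positive")
  expect_error(msp_rhs(replace(s0, 2, -0.1), p), "nonnegative")
})

test_that("rhs matches a finite difference of the integrated trajectory", {
  p <- msp_base_point()
  s <- c(E = 0.4, S0 = 3, S1 = 0.5, S2 = 0.2, ES0 = 0.1, ES1 = 0.16)
  # second-order one-sided difference: the mechanism is stiff enough that a
  # plain forward difference is dominated by curvature
  h <- 1e-8
  tr <- simulate_msp(p, ic = s, times = c(h, 2 * h), rtol = 1e-12,
                     atol = 1e-14)
  x0 <- s[c("E", "S0", "S1", "S2", "ES0", "ES1")]
  fd <- (4 * as.numeric(tr[1, -1]) - as.numeric(tr[2, -1]) - 3 * x0) / (2 * h)
  expect_equal(unname(fd), unname(msp_rhs(s, p)), tolerance = 1e-6)
})

test_that("full-model trajectories conserve mass and convert all substrate", {
  tr <- simulate_msp(msp_base_point(), times = c(seq(2, 20, 2), 2000))
  expect_equal(tr$E + tr$ES0 + tr$ES1, rep(0.66, nrow(tr)), tolerance = 1e-6)
  expect_equal(tr$S0 + tr$S1 + tr$S2 + tr$ES0 + tr$ES1, rep(5, nrow(tr)),
               tolerance = 1e-6)
  expect_true(all(diff(tr$S2) >= -1e-8))
  # long horizon: complete double phosphorylation
  expect_equal(tr$S2[nrow(tr)], 5, tolerance = 1e-3)
})

test_that("effective parameters reproduce the nominal triplet and its limits", {
  kap <- effective_parameters(msp_base_point())
  expect_equal(round(unname(kap["kappa1"]), 3), 0.467)
  # direct evaluation lands within 0.5 percent of the printed (0.232, 0.362)
  expect_equal(unname(kap["kappa2"]), 0.232, tolerance = 5e-3)
  expect_equal(unname(kap["pi"]), 0.362, tolerance = 5e-3)
  # kr2 -> 0: every complex that binds goes on to product
  p0 <- replace(msp_base_point(), "kr2", 1e-12)
  expect_equal(unname(effective_parameters(p0)["pi"]), 1, tolerance = 1e-12)
  # kappa scale linearly in enzyme concentration
  expect_equal(unname(effective_parameters(msp_base_point(), 1.32)[1:2]),
               unname(2 * kap[1:2]))
})

test_that("reduced model matches the matrix-exponential oracle", {
  skip_if_not_installed("Matrix")
  kap <- c(kappa1 = 0.467, kappa2 = 0.232, pi = 0.362)
  A <- matrix(c(-kap[1], 0, 0,
                (1 - kap[3]) * kap[1], -kap[2], 0,
                kap[3] * kap[1], kap[2], 0), 3, 3, byrow = TRUE)
  tr <- simulate_reduced(kap, times = seq(2, 20, 2))
  for (i in seq_len(nrow(tr))) {
    oracle <- as.numeric(Matrix::expm(A * tr$time[i]) %*% c(5, 0, 0))
    expect_equal(as.numeric(tr[i, c("S0", "S1", "S2")]), oracle,
                 tolerance = 1e-10)
  }
  # substrate conserved exactly
  expect_equal(tr$S0 + tr$S1 + tr$S2, rep(5, nrow(tr)))
})

test_that("reduced-model closed forms handle decoupled and degenerate cases", {
  times <- seq(0.5, 8, by = 0.5)
  # kappa2 ~ 0: S1 accumulates as (1 - pi) S0(0) (1 - exp(-kappa1 t))
  k <- c(kappa1 = 0.5, kappa2 = 1e-9, pi = 0.3)
  tr <- simulate_reduced(k, times = times)
  expect_equal(tr$S1, (1 - 0.3) * 5 * (1 - exp(-0.5 * times)),
               tolerance = 1e-6)
  # pi -> 1: no flux through S1
  tr2 <- simulate_reduced(c(kappa1 = 0.5, kappa2 = 0.2, pi = 1 - 1e-12),
                          times = times)
  expect_equal(tr2$S1, rep(0, length(times)), tolerance = 1e-9)
  # confluent limit kappa1 = kappa2 stays finite and conserves mass
  tr3 <- simulate_reduced(c(kappa1 = 0.4, kappa2 = 0.4, pi = 0.5),
                          times = times)
  expect_true(all(is.finite(as.matrix(tr3))))
  expect_equal(tr3$S0 + tr3$S1 + tr3$S2, rep(5, length(times)))
})

test_that("full model agrees with the QSSA reduction in the valid regime", {
  p <- msp_base_point()
  expect_true(qssa_validity(p, 5)$valid)
  full <- simulate_msp(p, times = seq(2, 20, 2))$S2
  red <- simulate_reduced(effective_parameters(p), times = seq(2, 20, 2))$S2
  expect_lt(max(abs(full - red) / red), 0.02)
})

test_that("caricature mechanism conserves mass and obeys limiting behavior", {
  k <- caricature_base_point()
  tr <- simulate_caricature(k, times = c(seq(2, 10, 2), 500))
  expect_equal(tr$E + tr$C, rep(0.66, nrow(tr)), tolerance = 1e-6)
  expect_equal(tr$S0 + tr$S1 + tr$C, rep(5, nrow(tr)), tolerance = 1e-6)
  expect_true(all(diff(tr$S1) >= -1e-8))
  expect_equal(tr$S1[nrow(tr)], 5, tolerance = 1e-3)
  # kcat ~ 0: no product ever forms
  tr0 <- simulate_caricature(c(kf = 0.97, kr = 7000, kcat = 1e-12),
                             times = seq(2, 10, 2))
  expect_equal(tr0$S1, rep(0, 5), tolerance = 1e-9)
  # kr -> infinity starves the complex: production collapses
  trb <- simulate_caricature(c(kf = 0.97, kr = 7e7, kcat = 10000),
                             times = seq(2, 10, 2))
  expect_true(all(trb$S1 < 0.01 * tr$S1[1:5] + 1e-6))
})

test_that("k_eff matches its closed form and the fast-binding limit", {
  expect_equal(k_eff(c(kf = 2, kr = 1e-15, kcat = 3), E_tot = 1.5), 3)
  # first caricature regime: kr << kcat, so k_eff is essentially E_tot * kf
  k1 <- caricature_base_point("k1")
  expect_equal(k_eff(k1) / 0.66, unname(k1["kf"]), tolerance = 3e-3)
  expect_equal(k_eff(caricature_base_point("k2")),
               0.66 * 0.97 * 10000 / 17000)
})

test_that("QSSA diagnostics flag valid and invalid regimes", {
  p <- msp_base_point()
  v <- qssa_validity(p, 5)
  expect_true(v$valid1 && v$valid2)
  expect_equal(qssa_validity(p, 0)$ratio1, 0)
  # very fast binding breaks the first condition
  pf <- replace(p, "kf1", 1e9)
  expect_false(qssa_validity(pf, 5)$valid1)
  # the as-printed variant uses (kf1 + kcat1)/kf1 and differs
  expect_false(isTRUE(all.equal(qssa_validity(p, 5)$ratio1,
                                qssa_validity(p, 5, as_printed = TRUE)$ratio1)))
})

test_that("base-point assignment resolves the printed rate ordering", {
  lab <- effective_parameters(msp_base_point("label_order"))
  # taking the printed vector in label order puts kappa2 three orders of
  # magnitude away from the nominal value; the consistent assignment does not
  expect_gt(unname(lab["kappa2"]), 100)
  expect_lt(abs(effective_parameters(msp_base_point())[["kappa2"]] - 0.232),
            0.002)
})
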