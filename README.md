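# effparam

Data-driven characterization of parameter (non)identifiability for kinetic
models observed only through input-parameter → output-time-series pairs.

Most kinetic models are *sloppy*: the output depends on a handful of
(generally nonlinear) parameter combinations — the **effective
parameters** — while the remaining combinations are **redundant**, tracing
out level sets of indistinguishable behavior in parameter space. Given an
ensemble of parameter vectors and the behaviors they produce, `effparam`

* counts the effective parameters as the intrinsic dimension of the *model
  manifold* (the set of attainable behavior vectors), using
  output-informed diffusion maps with parsimonious (nonharmonic)
  eigenvector selection;
* counts the redundant combinations from an ensemble of *equivalent
  optima* — independent least-squares refits of one reference transient —
  via PCA and parameter-space diffusion maps;
* builds smooth invertible maps between data-driven coordinates φ,
  candidate physical effective parameters κ, and behaviors, using
  geometric harmonics in diffusion coordinates ("Double DMaps") with
  Nystrom out-of-sample extension, plus a small tanh-network backend;
* disentangles effective from redundant combinations with a **conformal
  autoencoder** — a Y-shaped network whose latent coordinates are trained
  to have mutually orthogonal input-gradients, with the behavior estimator
  wired to the effective block only — and traces explicit level sets of
  constant behavior in full parameter space from its decoder;
* extracts effective parameters as **jointly smooth functions** (JSFs)
  over a pair of views (output measurements; parameter vectors), scores
  near √2 marking functions smooth over both, and returns the orthogonal
  complement as the redundant combinations.

Three mass-action testbeds are built in, so every claim can be exercised
end to end on simulated data: a six-parameter dual-phosphorylation
mechanism (ERK phosphorylated twice by MEK), whose QSSA reduction depends
on three effective parameters

    kappa1 = [E] kf1 kcat1 / (kr1 + kcat1)
    kappa2 = [E] kf2 kcat2 / (kr2 + kcat2)
    pi     = kcat2 / (kr2 + kcat2)

(at the base point with [E] = 0.66: κ = (0.467, 0.231, 0.361)); a
single-site caricature `S0 + E ⇌ C → S1 + E` with the single effective
parameter `k_eff = E_tot kf kcat/(kr + kcat)`; and an analytic toy
`f = exp(-p1 p2 / 2)` with effective combination φ = p1·p2 and conformal
redundant combination ψ = p1² − p2².

## Worked example

Count the effective parameters of the caricature from data, then inspect
the effective coordinate:

```r
library(effparam)

P  <- sample_parameters(caricature_base_point(), fraction = 0.2,
                        n = 2000, seed = 3)
ds <- build_transient_dataset(P, "caricature", times = seq(2, 10, 2),
                              observable = "S1")
id <- intrinsic_dimension(ds, "output_informed")
id$dimension
#> [1] 1

keff <- apply(as.matrix(P), 1, function(p) {
  names(p) <- colnames(P); k_eff(p)
})
cor(id$model$vectors[, 2], keff[id$rows], method = "spearman")
#> [1] -0.9999998
```

One eigenvector survives the parsimonious test — the system has a single
effective parameter — and it is one-to-one with the analytic `k_eff`:
manifold learning rediscovers the QSSA combination without seeing it.

The full studies are packaged:

```r
rep <- run_caricature_study(seed = 2)      # ~40 s: dimension + autoencoder
rep$dimension                               # 1
rep$nu1_keff_spearman                       # 1.0000
rep$level_set_behavior_deviation            # 0.00146 (behavior pinned ...)
rep$level_set_parameter_extent              # 0.385   (... while rates move 38%)

rep <- run_msp_study(seed = 1)              # minutes: transient + optima + maps
```

`vignettes/effective-parameters.Rmd` documents the models, the algorithms
and every tuning default.

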