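# Shared fixtures, generated once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# dual-phosphorylation transient ensemble at the study conditions
# (perturbation +/-10 percent, [S2] at t = 2..20), scaled to n samples
msp_ensemble <- function(n = 6000, seed = 11) {
  fixture(sprintf("msp_%d_%d", n, seed), function() {
    P <- sample_parameters(msp_base_point(), 0.1, n, seed = seed)
    build_transient_dataset(P, "msp", base = msp_base_point(),
                            fraction = 0.1, seed = seed)
  })
}

msp_dimension <- function(n = 6000, seed = 11) {
  fixture(sprintf("msp_dim_%d_%d", n, seed), function() {
    intrinsic_dimension(msp_ensemble(n, seed), "output_informed")
  })
}

kappa_of <- function(parameters) {
  t(apply(as.matrix(parameters), 1, function(p) {
    names(p) <- colnames(parameters)
    effective_parameters(p)
  }))
}

caricature_ensemble <- function(n = 2000, seed = 3) {
  fixture(sprintf("car_%d_%d", n, seed), function() {
    P <- sample_parameters(caricature_base_point(), 0.2, n, seed = seed)
    build_transient_dataset(P, "caricature", times = seq(2, 10, by = 2),
                            observable = "S1", base = caricature_base_point(),
                            fraction = 0.2, seed = seed)
  })
}

keff_of <- function(parameters) {
  apply(as.matrix(parameters), 1, function(p) {
    names(p) <- colnames(parameters)
    k_eff(p)
  })
}
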