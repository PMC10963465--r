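# Shared fixtures, built once per test run. All fixtures are constructed in
# code; the heavier solves are memoised.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

default_materials <- function() {
  list(media = medial_material(), adventitia = adventitial_material())
}

# Representative example-case G&R parameters (transient, local).
example_params <- function() {
  growth_parameters(k_sigma = 0.130, k_gplus_c = 5.34, k_gminus_c = 3.67,
                    k_gminus_e = 0.0533, delta = 0.198, beta = 1.24)
}

# Stress-only parameters: all inflammation gains zero.
stress_only_params <- function(k_sigma = 0.42) {
  growth_parameters(k_sigma = k_sigma, k_gplus_c = 0, k_gminus_c = 0,
                    k_gminus_e = 0, delta = 0.198, beta = 1.24)
}

healthy_state <- function() {
  memo("healthy", solve_healthy_invivo_state())
}

dissected_state <- function() {
  memo("dissected", dissect(healthy_state()))
}

example_result <- function() {
  memo("example_result",
       run_simulation(example_params(),
                      inflammation_pattern("transient", "local")))
}

# Elastin-only (neo-Hookean) material: no collagen contribution.
elastin_only_material <- function(c10 = 0.015, layer = "media") {
  layer_material(c10 = c10, k1 = 0, k2 = 1, alpha = 0,
                 rho0_e = 1, rho0_c = 0, layer = layer)
}
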