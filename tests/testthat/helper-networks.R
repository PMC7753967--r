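# Shared fixtures built in code.

# Single-substrate catalytic network S -> Q for rate-law comparisons.
single_substrate_network <- function(k_cat = 1.46e4, k_act = 90, k_rev = 0,
                                     k_inact = 0, fe_total = 1e-6,
                                     h2o2 = 5e-3) {
  reaction_network(
    species = data.frame(id = c("S", "Q"), name = c("substrate", "product"),
                         formula = c("C10H8O", "C10H6O2"),
                         terminal = c(FALSE, TRUE)),
    catalytic_steps = data.frame(substrate = "S", product = "Q",
                                 k_cat = k_cat),
    catalyst = list(total_conc = fe_total, k_act = k_act, k_rev = k_rev,
                    k_inact = k_inact),
    oxidant_conc0 = h2o2, constant_oxidant = TRUE
  )
}

# Two consecutive pseudo-first-order direct steps S1 -> S2 -> S3 with
# effective rates a and b (k_direct = rate / [H2O2], oxidant held constant).
chain_network <- function(a, b, h2o2 = 5e-3) {
  reaction_network(
    species = data.frame(id = c("S1", "S2", "S3"),
                         formula = c("C2H2O4", "C2H2O4", "C2H2O4"),
                         terminal = c(FALSE, FALSE, TRUE)),
    direct_steps = data.frame(substrate = c("S1", "S2"),
                              product = c("S2", "S3"),
                              k_direct = c(a, b) / h2o2),
    catalyst = list(total_conc = 0, k_act = 0, k_rev = 0, k_inact = 0),
    oxidant_conc0 = h2o2, constant_oxidant = TRUE
  )
}

reference_profile <- local({
  cache <- NULL
  function(by = 5) {
    if (is.null(cache)) {
      net <- propranolol_network()
      cache <<- simulate_network(net, initial_state(net, conc = c(P = 5e-5)),
                                 times = seq(0, 8 * 3600, by = by))
    }
    cache
  }
})

noiseless_observations <- function(scen = default_scenario()) {
  generate_observations(scen$network, scen$init, scen$sample_times,
                        noise = noise_model(0, 0), lod = 0)
}
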