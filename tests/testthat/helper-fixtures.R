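# Shared fixtures: tiny networks with known structure, built in code.

# two-population toy network: aerobic glucose growth (bin P) and aerobic
# acetate growth (bin Q), plus the compound registry they use
toy_two_bin_network <- function() {
  ctx <- energy_context()
  r1 <- couple_halves(half_reaction(c(glucose = -1, O2 = -6, CO2 = 6, H2O = 6)),
                      "glucose", ctx, chain = "canonical", id = "p1",
                      population = "P", scenario = "both")
  r2 <- couple_halves(half_reaction(c(acetate = -1, O2 = -2, H = -1,
                                      CO2 = 2, H2O = 2)),
                      "acetate", ctx, chain = "canonical", id = "q1",
                      population = "Q", scenario = "both")
  reaction_network(list(r1, r2))
}

# single-reaction network (aerobic glucose, Y ~ 0.62)
toy_single_network <- function() {
  ctx <- energy_context()
  r <- couple_halves(half_reaction(c(glucose = -1, O2 = -6, CO2 = 6, H2O = 6)),
                     "glucose", ctx, chain = "canonical", id = "only",
                     population = "P", scenario = "both")
  reaction_network(list(r))
}

# sparse true rates with identifiable support on the default network
default_vstar <- function() c(d = 0.3, i = 0.8, r = 1.2, u = 0.4, w = 0.15)
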