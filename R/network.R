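# The default communal metabolic network: a reconstruction of the
# tidal-chemostat community from its described gene activities.
#
# Populations (genome bins):
#   A  Rhodobacterales: aerobic respiration (cbb3, canonical chain) and
#      nitrite -> N2O denitrification of organic substrates incl. glucose
#   B  Arcobacter I: formate/H2 aerobic respiration (cbb3), nitrate ->
#      nitrite and N2O -> N2 on acetate, sulfide -> S0 oxidation
#   C  Arcobacter II: nitrate -> nitrite and N2O -> N2 on formate
#   D  Vibrio: mixed-acid fermentation of glucose, aerobic respiration with
#      the non-pumping cytochrome bd oxidase
#   E  Desulfovibrio: sulfate reduction on acetate
#   F  Firmicutes: fermentation of glucose + alanine, serine, and of the
#      remaining amino acids to succinate, with H2 evolution
# plus a glucose -> storage-glucan reaction not assigned to any bin.
# Reactions a-c are the thermodynamically sorted scenario: canonical
# respiration of the complete supplied carbon mixture with O2, nitrite and
# nitrate; reactions d onward form the unsorted ('braided') scenario.

#' Construct a reaction network object
#'
#' @param reactions List of [metabolic_reaction]s.
#' @param compounds Compound registry used by the reactions.
#' @return Object of class `reaction_network`.
#' @export
reaction_network <- function(reactions, compounds = default_compounds()) {
  stopifnot(all(vapply(reactions, inherits, logical(1), "metabolic_reaction")))
  ids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate reaction ids")
  names(reactions) <- ids
  structure(list(reactions = reactions, compounds = compounds),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network> %d reactions, %d compounds\n",
              length(x$reactions), length(x$compounds)))
  for (r in x$reactions)
    cat(sprintf("  %-3s bin %-8s %-8s Y=%.3f  %s\n", r$id, r$population,
                r$scenario, r$yield_Y, format_stoich(r$net_stoich)))
  invisible(x)
}

#' Net stoichiometric matrix of a network
#'
#' @param network A [reaction_network].
#' @param species Optional compound ids for the rows; defaults to every
#'   compound appearing in the network except water and protons.
#' @return Matrix, species x reactions.
#' @export
stoich_matrix <- function(network, species = NULL) {
  rxns <- network$reactions
  if (is.null(species)) {
    species <- unique(unlist(lapply(rxns, function(r) names(r$net_stoich))))
    species <- setdiff(species, c("H2O", "H"))
  }
  S <- matrix(0, length(species), length(rxns),
              dimnames = list(species, names(rxns)))
  for (j in seq_along(rxns)) {
    st <- rxns[[j]]$net_stoich
    st <- st[names(st) %in% species]
    S[names(st), j] <- st
  }
  S
}

# -- catabolic half skeletons -------------------------------------------------

# oxidation of one formula unit of `donor` with `acceptor`, fixed products
# of interest, remainder balanced by CO2/H2O/H+/NH4+/HS-.
respiration_half <- function(donor, acceptor = c("O2", "NO2_N2O", "NO2_N2",
                                                 "NO3_NO2", "NO3_N2", "N2O_N2",
                                                 "SO4_HS"),
                             compounds = default_compounds()) {
  acceptor <- match.arg(acceptor)
  e_don <- electrons_per_mol(compounds[[donor]])
  fixed <- switch(acceptor,
    O2      = c(O2  = -e_don / 4),
    NO2_N2O = c(NO2 = -e_don / 2, N2O = e_don / 4),    # NO2- -> 1/2 N2O: 2 e-
    NO2_N2  = c(NO2 = -e_don / 3, N2 = e_don / 6),     # NO2- -> 1/2 N2 : 3 e-
    NO3_NO2 = c(NO3 = -e_don / 2, NO2 = e_don / 2),    # NO3- -> NO2-   : 2 e-
    NO3_N2  = c(NO3 = -e_don / 5, N2 = e_don / 10),    # NO3- -> 1/2 N2 : 5 e-
    N2O_N2  = c(N2O = -e_don / 2, N2 = e_don / 2),     # N2O  -> N2     : 2 e-
    SO4_HS  = c(SO4 = -e_don / 8, HS = e_don / 8))     # SO4  -> HS-    : 8 e-
  skeleton <- c(setNames(-1, donor), fixed)
  # NH4+ takes amino-acid nitrogen, HS- organic sulfur; both carry zero
  # available electrons, so the acceptor stoichiometry fixed above stands
  half_reaction(balance_skeleton(skeleton, c("CO2", "H2O", "H", "NH4", "HS"),
                                 compounds),
                "catabolic", compounds)
}

# fermentation with fixed product slate; H2O/H+/CO2/NH4+ balanced.
fermentation_half <- function(skeleton, compounds = default_compounds(),
                              balance_with = c("CO2", "H2O", "H", "NH4")) {
  half_reaction(balance_skeleton(skeleton, balance_with, compounds),
                "catabolic", compounds)
}

# sulfide oxidation to elemental sulfur (pure catabolic conversion)
sulfide_oxidation_half <- function(compounds = default_compounds()) {
  half_reaction(balance_skeleton(c(HS = -1, O2 = -0.5, S0 = 1),
                                 c("H2O", "H"), compounds),
                "catabolic", compounds)
}

# weighted whole-medium oxidation (sorted scenario): one C-mol of the
# supplied carbon mixture oxidized with the given acceptor.
mixture_catabolic <- function(acceptor, med = default_medium(),
                              compounds = default_compounds()) {
  w <- medium_cmol_weights(med, compounds)
  parts <- lapply(names(w), function(id) {
    per_cmol <- w[[id]] / compounds[[id]]$carbon_count  # mol of compound
    per_cmol * respiration_half(id, acceptor, compounds)$stoich
  })
  half_reaction(do.call(add_stoich, parts), "catabolic", compounds)
}

# weighted whole-medium assimilation producing 1 C-mol biomass
mixture_anabolic <- function(med = default_medium(),
                             compounds = default_compounds()) {
  w <- medium_cmol_weights(med, compounds)
  parts <- lapply(names(w), function(id)
    w[[id]] * anabolic_half(id, compounds)$stoich)
  half_reaction(do.call(add_stoich, parts), "anabolic", compounds)
}

# C-mol fractions of the carbon compounds in a medium
medium_cmol_weights <- function(med, compounds) {
  conc <- med$concentrations
  cc <- vapply(names(conc), function(id) compounds[[id]]$carbon_count, numeric(1))
  w <- conc * cc
  w <- w[w > 0]
  w / sum(w)
}

# dissipation demand of the mixture: C-mol-weighted mean over substrates
mixture_dissipation <- function(med, compounds) {
  w <- medium_cmol_weights(med, compounds)
  sum(vapply(names(w), function(id) {
    cp <- compounds[[id]]
    w[[id]] * dissipation_correlation(cp$carbon_count, degree_of_reduction(cp))
  }, numeric(1)))
}

# amino-acid side pool (all medium amino acids except alanine and serine),
# fermented to succinate + acetate + H2 per 1 C-mol of the pool.
aa_pool_fermentation <- function(med = default_medium(),
                                 compounds = default_compounds()) {
  pool <- c("glutamate", "aspartate", "tyrosine", "histidine", "methionine")
  conc <- med$concentrations[pool]
  cc <- vapply(pool, function(id) compounds[[id]]$carbon_count, numeric(1))
  w <- conc * cc / sum(conc * cc)            # C-mol fractions within pool
  donors <- setNames(-w / cc, pool)          # mol per 1 C-mol of pool
  # product slate: succinate main (0.15 mol = 0.6 C), acetate 0.15 mol
  skeleton <- c(donors, succinate = 0.15, acetate = 0.15)
  fermentation_half(skeleton, compounds,
                    balance_with = c("CO2", "H2O", "H", "NH4", "HS", "H2"))
}

#' The default communal metabolic network
#'
#' Builds the ~25-reaction reconstruction of the tidal-chemostat community
#' (see the package vignette for the full rationale): per-population
#' respiration, denitrification, fermentation, sulfate reduction, sulfide
#' oxidation and storage reactions, each coupled to biomass formation via
#' [couple_halves()] with the respiratory chain appropriate to the
#' population (canonical cbb3 for bins A-C, cytochrome bd for Vibrio,
#' the denitrification chain for N-oxide reductions, substrate-level
#' phosphorylation for fermentation and sulfate reduction).
#'
#' @param med The [medium] defining the sorted-scenario mixture reactions.
#' @param ctx An [energy_context].
#' @return A [reaction_network].
#' @export
default_network <- function(med = default_medium(), ctx = energy_context()) {
  cps <- ctx$compounds
  mix_ctx <- energy_context(ctx$temperature, cps,
                            dissipation_override = mixture_dissipation(med, cps))
  mix_an <- mixture_anabolic(med, cps)

  cpl <- function(id, cat, an, chain, pop, scen)
    couple_halves(cat, an, ctx, chain = chain, id = id, population = pop,
                  scenario = scen)
  resp <- function(id, donor, acceptor, chain, pop, scen = "unsorted")
    cpl(id, respiration_half(donor, acceptor, cps), donor, chain, pop, scen)
  pure <- function(id, cat, pop, scen = "unsorted")
    metabolic_reaction(id, cat, NULL, population = pop, scenario = scen,
                       compounds = cps)

  rxns <- list(
    # sorted scenario: canonical respiration of the complete mixture
    couple_halves(mixture_catabolic("O2", med, cps), mix_an, mix_ctx,
                  chain = "canonical", id = "a", population = "A",
                  scenario = "sorted"),
    couple_halves(mixture_catabolic("NO2_N2", med, cps), mix_an, mix_ctx,
                  chain = "denitrification", id = "b", population = "A",
                  scenario = "sorted"),
    couple_halves(mixture_catabolic("NO3_N2", med, cps), mix_an, mix_ctx,
                  chain = "denitrification", id = "c", population = "A",
                  scenario = "sorted"),
    # bin A: aerobic respiration (cbb3) and nitrite -> N2O denitrification
    resp("d", "succinate", "O2",      "canonical",       "A"),
    resp("e", "acetate",   "O2",      "canonical",       "A"),
    resp("f", "glucose",   "O2",      "canonical",       "A"),
    resp("g", "succinate", "NO2_N2O", "denitrification", "A"),
    resp("h", "acetate",   "NO2_N2O", "denitrification", "A"),
    resp("i", "formate",   "NO2_N2O", "denitrification", "A"),
    resp("j", "glucose",   "NO2_N2O", "denitrification", "A"),
    # bin B: Arcobacter I
    resp("k", "formate", "O2",      "canonical",       "B"),
    pure("l", respiration_half("H2", "O2", cps), "B"),
    resp("m", "acetate", "NO3_NO2", "denitrification", "B"),
    resp("n", "acetate", "N2O_N2",  "denitrification", "B"),
    pure("o", sulfide_oxidation_half(cps), "B"),
    # bin C: Arcobacter II
    resp("p", "formate", "NO3_NO2", "denitrification", "C"),
    resp("q", "formate", "N2O_N2",  "denitrification", "C"),
    # bin D: Vibrio - mixed-acid fermentation + bd-terminated respiration
    cpl("r", fermentation_half(c(glucose = -1, formate = 2, acetate = 2, H2 = 2),
                               cps), "glucose", NULL, "D", "unsorted"),
    resp("s", "acetate", "O2", "bd", "D"),
    # bin F: Firmicutes - co-fermentations with H2 evolution
    cpl("t", fermentation_half(c(glucose = -1, alanine = -2, formate = 4,
                                 acetate = 4, H2 = 4), cps),
        "glucose", NULL, "F", "unsorted"),
    cpl("u", fermentation_half(c(serine = -1, formate = 1, acetate = 1), cps),
        "serine", NULL, "F", "unsorted"),
    cpl("v", aa_pool_fermentation(med, cps), "glutamate", NULL, "F", "unsorted"),
    # bin E: Desulfovibrio - sulfate reduction on acetate
    resp("w", "acetate", "SO4_HS", NULL, "E"),
    # storage: glucose condensed to a glucan, not assigned to a population
    metabolic_reaction("x",
      half_reaction(balance_skeleton(c(glucose = -1, storage = 1),
                                     c("H2O", "H"), cps), "catabolic", cps),
      NULL, population = "storage", scenario = "unsorted", compounds = cps)
  )
  reaction_network(rxns, cps)
}
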