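# braidmet

Stoichiometric modelling of *braided* microbial community metabolism in
oxygen-pulsed ("tidal") chemostats.

In sediments and chemostats exposed to oxygen gradients, the textbook
expectation is the microbial redox tower: oxygen respired first, then
nitrate/nitrite, with fermentation and sulfate reduction pushed into anoxic
niches. A marine-sediment community cycled for 100 days in a chemostat fed
20 mM nitrite, 1 mM nitrate, 6 mM glucose, 3.1 mM acetate and seven amino
acids at a dilution rate of 0.26 d⁻¹, with a 5-minute pure-oxygen pulse
every 12 h, instead *braids* its redox processes: fermenters (Vibrio,
Firmicutes) take the best substrates and excrete formate, acetate,
succinate and H2, which respirers and denitrifiers (Rhodobacterales,
Arcobacter) and sulfate reducers (Desulfovibrio) consume in parallel —
even while oxygen is present. braidmet is a toolkit for the quantitative
side of that analysis, aimed at microbial ecologists and biogeochemists
who want to interrogate community conversions with a balanced
stoichiometric model.

At its core is a communal metabolic model. Each reaction couples a
catabolic and an anabolic half per C-mol of biomass x,

    net = anabolic + λ·catabolic ,   λ·eff·(−ΔG_cat) = D_diss + ΔG_an ,

with the dissipation demand D_diss(C, γ) = 200 + 18·|6−C|^1.8 +
exp(((3.8−γ)²)^0.16·(3.6+0.4C)) kJ per C-mol biomass, and eff the
respiratory-chain efficiency q·pmf/(2·ΔE) (canonical chain q = 10,
cytochrome *bd* q = 4, denitrification q = 6). Non-negative reaction rates
v are then fitted to observed net conversions b by weighted, Tikhonov-
regularized non-negative least squares,

    min ‖W(Sv − b)‖² + ε‖v‖² ,  v ≥ 0 ,

and the fit reports the community biomass yield (C-mol assimilated per
C-mol consumed), per-population growth shares, and a comparison of the
thermodynamically *sorted* scenario (canonical respiration of the whole
carbon mixture) against the *unsorted* braided network.

## Worked example

```r
library(braidmet)

net <- default_network()           # bins A-F + storage, reactions a-x
obs <- observed_conversions()      # printed medium x 0.26/d, full consumption
cmp <- scenario_compare(net, obs)
cmp
#> <scenario_comparison>
#>  scenario residual_norm community_yield
#>    sorted     1.0854548       0.4512094
#>  unsorted     0.7076031       0.3118449
#> better match (lower residual): unsorted

cmp$fits$unsorted
#> <community_fit> scenario 'unsorted', 21 reactions
#>   residual norm (weighted): 0.7076
#>   community yield: 0.312 C-mol/C-mol
#>   abundances: A=0.77 B=0.14 C=0.02 D=0.02 F=0.06 E=0.00
```

The braided (unsorted) network explains the observed conversions better —
the sorted reactions can neither produce the observed fermentation
intermediates nor consume the full carbon supply within the electron-
acceptor budget — and its fitted community yield, **0.312 C-mol/C-mol**, is
a model *output* (growth is not fitted) matching the low yield measured
for the assembled community (0.32 ± 0.02 from day 83). The sorted scenario
would have been far more productive (0.451): the community trades
productivity for resilience.

Supporting calculators behave the same way:

```r
100 * chain_efficiency("bd")    # 31.6  -- % efficiency of a bd-terminated
                                #          chain at 180 mV (canonical: 78.9)
depletion_threshold(fmol_day_to_mol_s(25), r_obj = 0.5e-6) / 1e-6
#> 43.7                          -- nM bulk O2 below which a 1-um cell
#>                                  can deplete its surroundings
```

A 1-µm cell respiring at the community's maximal rate only becomes
diffusion-limited in the low-nanomolar range, which is why *aggregates*
(whose thresholds are orders of magnitude higher) are needed to shelter
oxygen-sensitive enzymes in oxic bulk water.

A seeded synthetic-data module (`simulate_cycle()`,
`generate_observations()`, `generate_counts()`) generates tidal-cycle
concentration trajectories, conversion vectors from known rate vectors and
read-count tables from known per-ORF activities, so the whole pipeline is
testable against ground truth. See the vignette
(`vignettes/braided-metabolism.Rmd`) for the model derivations, parameter
choices and limitations.

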