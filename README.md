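# phenostab

Simulation toolkit for studying how the **seasonal organization of
mutualistic interactions** — who interacts with whom *in which month* —
affects the stability of bipartite plant–hummingbird networks.

Time-aggregated interaction networks hide the fact that two hummingbirds
sharing a plant only compete for it when they visit it in the same months,
and that a plant benefits from a bird only while both are active.
`phenostab` encodes this with phenological overlap indices derived from
monthly interaction counts, feeds them into an obligate-mutualism community
model, integrates it to its ecological equilibrium, and compares four
facets of stability with and without the seasonal structure:

- **feasibility** — share of growth-rate draws for which (almost) the whole
  community coexists (persistence > 98%),
- **persistence** — percentage of species above the extinction threshold
  (10⁻⁵) at equilibrium (as a count: diversity),
- **resilience** — −max Re(λ) of the equilibrium Jacobian restricted to
  survivors (inverse return time after a small perturbation),
- **robustness** — mean share of remaining species surviving the forced
  removal of one hummingbird, after re-equilibration.

## The model

Hummingbird abundances H and flower abundances P follow (plants symmetric):

    dHj/dt = Hj ( rj + α Σi Iij Oij Pi / (1 + β Σi Iij Oij Pi + c Σk Ωkj Hk)
                     − Σk cs_{j,k} Hk )

with binary backbone *I*, among-guild phenological overlap *O*, handling
time β = 0.8, mutualism strength α, and competition for mutualistic
partners of maximal strength *c* acting through abundance-weighted
coefficients Ω (birds) and Θ (plants) built from the within-guild overlap
arrays *Mh*, *Mp*. Growth rates are negative (obligate mutualism), drawn as
−½·Beta(1, b) with b ~ exp U(log 0.3, log 15) per guild and replicate.
Setting every entry of *O*, *Mh*, *Mp* to one removes the seasonal
structure; paired simulations differing only in that respect quantify its
effect. A factorial grid (communities × 250 replicates × 7 α × 7 c ×
2 modes = 269,500 runs at full scale), a phenology-randomization null
model, equilibrium network indices, and a mixed-model path analysis
(attributing stability effects to diversity, connectance, interaction
overlap and total abundance) complete the pipeline. Details and rationale
are in the vignette (`vignettes/seasonal-network-stability.Rmd`).

## Worked example

```r
library(phenostab)

# synthetic community with the dimensions of the Alaspungo network
tab <- generate_community(community_preset("Alaspungo"), seed = 1)
tab
#> Interaction table: 40 plants x 7 hummingbirds, 113 links
#>   active months/species: plants 8.4, hummingbirds 9 (mean)

s <- seasonal_structure(tab)
s
#> Seasonal structure (40 plants x 7 hummingbirds, convention 'printed')
#>   mean among-guild overlap O: 0.444

# one growth-rate replicate, strong mutualism and competition
gr <- list(r_h = sample_growth_rates(7, seed = 7),
           r_p = sample_growth_rates(40, seed = 8))
p <- model_parameters(alpha = 2, comp = 2, r_p = gr$r_p, r_h = gr$r_h)

with_season <- integrate_to_equilibrium(tab, s, p)
without     <- integrate_to_equilibrium(tab, flat_structure(tab), p)

persistence(with_season)   # 97.9  (% of the 47 species surviving)
persistence(without)       # 78.7
relative_change(persistence(with_season), persistence(without))
#> +24.3 %  -- seasonal structure lets more species coexist here

resilience(with_season, tab, s, p)                        # 0.027
resilience(without, tab, flat_structure(tab), p)          # 0.019
```

(The persistence/resilience numbers above are for the seeds shown in this
README's session; the qualitative pattern — seasonality helping when both
mutualism and competition are strong — is what the test suite asserts with
bootstrap confidence intervals.)

Batch experiments go through the grid:

```r
spec <- desk_design_spec(master_seed = 1)   # 2 communities x 25 replicates
records <- run_design(spec)                 # one row per simulation
mode_contrast(records, "persistence")       # with/without heatmap cells
combos <- select_combinations(records)      # cells for path analysis
fit <- fit_path_analysis(records[records$alpha == 2 & records$c == 2, ])
```

## Layout

- `R/` — community synthesis, seasonal overlap indices, dynamics,
  stability metrics, network indices, experiment grid, path analysis
- `tests/testthat/` — unit, property and end-to-end suites with
  independent brute-force oracles
- `vignettes/seasonal-network-stability.Rmd` — the methods vignette
- `scripts/acceptance.R` — headline-quantity reproduction script
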