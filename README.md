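# ecoassembly

Community-assembly inference for soil microbiome surveys: who shapes a
metacommunity — the environment, dispersal, drift, or the organisms
themselves?

`ecoassembly` is an R package plus a set of numbered analysis scripts
that re-implement, as tested and reusable code, the inference chain
used in arid-soil microbial biogeography:

* **Assembly null models** — abundance-weighted βMNTD with a
  tip-shuffle null gives the beta nearest taxon index
  (βNTI = (obs − mean(null)) / sd(null)); the abundance-based
  Raup-Crick metric (RC<sub>bray</sub>) locates observed Bray-Curtis
  dissimilarity inside a richness- and depth-preserving null. The
  quoted rule table (βNTI < −2 homogeneous selection, βNTI > 2
  variable selection; otherwise RC > 0.95 dispersal limitation,
  RC < −0.95 homogenizing dispersal, |RC| < 0.95 drift) classifies
  every sample pair, and process fractions summarize the landscape.
* **Cohesion** — per-sample positive/negative cohesion
  `Σᵢ abundanceᵢ × connectednessᵢ`, with connectedness from
  null-corrected pairwise correlations.
* **RMT co-occurrence networks** — the correlation threshold is chosen
  where the adjacency spectrum's nearest-neighbour eigenvalue spacings
  turn from the Wigner-Dyson (GOE) form to the Poisson form; topology
  features, greedy modules and Zi/Pi node roles follow.
* **Spatial eigenfunctions** — great-circle distances, dbMEM/PCNM
  construction (MST truncation, 4t replacement, positive-eigenvalue
  principal coordinates), Moran's I screening, detrending, and
  forward selection with a double stopping criterion.
* **Attribution** — Mantel and partial Mantel tests, distance-decay
  regression with residual permutation, multiple regression on
  distance matrices, and three-way variation partitioning of adjusted
  R² across environment, space and biotic interactions.
* **Synthetic metacommunities** — a generator that plants selection,
  dispersal limitation, or drift on the emulated survey layout
  (69 plots, 3 regions × 2 habitats, fixed depth J) with
  phylogenetically conserved niches, so every downstream stage is
  testable against known ground truth without any sequencing data.

## Worked example

```r
library(ecoassembly)

cfg <- scenario_config(mode = "selection", seed = 11)  # 69 x 150, J = 1000
sim <- simulate_metacommunity(cfg)

b  <- bnti(sim$table, sim$tree, n_null = 199, seed = 1)
rc <- raup_crick_bray(sim$table, n_null = 199, seed = 1)
fr <- process_fractions(classify_processes(b, rc))
round(fr$fractions, 2)
#>     variable_selection  homogeneous_selection   dispersal_limitation
#>                   0.00                   0.85                   0.00
#> homogenizing_dispersal                  drift
#>                   0.01                   0.14
```

The scenario plants homogeneous selection (a shared environment filters
a phylogenetically coherent fifth of the taxon pool), and the null
models assign 85 % of the 2,346 sample pairs to homogeneous selection —
the planted process is the modal class. The same chain on the
drift-planted scenario puts 94 % of pairs in drift, and the
dispersal-planted scenario 82 % in dispersal limitation (see
`results/assembly_fractions.tsv` after running the analysis scripts).

The full analysis lives in `analysis/01_simulate.R` …
`analysis/06_attribution.R`; each script is a thin narrative driver
over the package functions and writes its tables under `results/`.

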