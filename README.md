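# mhcsupertypes

Does balancing selection on MHC *supertypes* — clusters of alleles with
similar antigen-binding properties — explain trans-species polymorphism
(TSP), the persistence of MHC allelic lineages across species
boundaries? `mhcsupertypes` implements the full computational toolkit
needed to interrogate that hypothesis, for evolutionary geneticists and
molecular ecologists working on MHC diversity:

* **Coevolution simulator** — an individual-based host–parasite model in
  a 2-D paratope space. Diploid hosts carry two allele coordinates on a
  1000 × 1000 grid; parasites are single coordinates; an allele
  recognises a parasite with probability `exp(-d² / 2s²)` in Euclidean
  distance `d`. Hosts reproduce in proportion to the fraction of
  parasites they recognise (best-allele rule), parasites in proportion
  to their escape probability. Scenario presets vary mutation rates,
  population size, the 1% random seeding of the parasite pool, parasite
  neutrality, and the number of parasite species.
* **Supertype analysis** — single-linkage delimitation of supertype
  clusters in paratope space, centroid/lineage tracking
  (persist/move/loss/branch events), and the effective number of
  alleles (inverse Simpson, `1/Σp²`).
* **Population genetics** — pairwise Jost's D
  (`D = 2(H_T − H_S)/(1 − H_S)`, naive or Nei–Chesser-corrected),
  observed vs. label-randomized supertype structure per population,
  per-supertype jackknives with Spearman concordance, three
  randomized-deletion controls, and supertype-homozygosity fractions.
* **Phylogenetics** — Jukes–Cantor distances
  (`d = −¾ ln(1 − 4p/3)`, pairwise deletion), neighbour-joining trees,
  column-bootstrap support, and a per-supertype monophyly report on the
  unrooted tree.
* **Synthetic data** — seed-deterministic generators for aligned
  sequences (monophyletic vs. convergent supertype scenarios, with the
  true tree returned) and multi-population genotype tables (structured
  supertypes plus an optional unstructured high-frequency outlier), so
  every pipeline is testable without downloads.

## Worked example

```r
library(mhcsupertypes)

# neutral yardstick: at the original model's mutation rate, heterozygosity
# is essentially saturated even without selection
expected_heterozygosity(Ne = 1e4, mu = 1e-1)
#> [1] 0.9997501

# run the original high-mutation / 1%-seeding scenario (~1 min)
sim <- run_scenario("original", seed = 1)
glance(sim)
#> # A tibble: 1 × 7
#>   generations host_pop_size n_parasite_species median_supertypes median_alleles
#>         <int>         <int>              <int>             <int>          <int>
#> 1         600          2500                  1                 4           1000
#>   median_effective_alleles n_log_events
#>                      <dbl>        <int>
#> 1                     55.9            0
```

`median_supertypes` is the number of single-linkage allele clusters in
paratope space over the second half of the run, and
`median_effective_alleles` the inverse-Simpson allele count in samples
of 100 individuals — the two headline diversity statistics of the
model. `autoplot(sim)` draws both trajectories;
`plot_paratope_space(sim)` shows the final configuration of host
supertypes and parasites on the grid.

```r
# population-genetic signature of an unstructured outlier supertype
set.seed(1)
tab <- sim_genotype_tables()          # 6 populations, outlier "ST_out"
jk  <- jackknife_supertypes(tab$genotypes, tab$st_map, n_reps = 200)
tidy(jk)[, c("supertype", "mean_diff", "spearman_rho")]
#> # A tibble: 8 × 3
#>   supertype mean_diff spearman_rho
#>   <chr>         <dbl>        <dbl>
#> 1 (none)       -0.180        1
#> 2 ST_out       -0.325        0.486
#> 3 ST1          -0.159        0.771
#> 4 ST2          -0.152        0.886
#> 5 ST3          -0.156        0.943
#> 6 ST4          -0.151        0.886
#> 7 ST5          -0.158        1
#> 8 ST6          -0.157        0.943
```

`mean_diff` is the mean per-population gap between observed
supertype-level structure and its label-randomization expectation
(`(none)` = full dataset). Removing any structured supertype barely
moves it (−0.15 to −0.16), but removing the shared, high-frequency
outlier supertype shifts it far more (−0.325) and breaks the rank
concordance with the full dataset (ρ = 0.49) — the dataset-level
signal is driven by that single supertype, which is precisely the
diagnostic the jackknife is for.

```r
# monophyly: convergent supertype labels are not clades
set.seed(1)
g    <- sim_supertype_alignment("convergent_supertypes")
tree <- bootstrap_support(g$alignment, n_reps = 100)
rep  <- supertype_monophyly_report(tree, g$st_map)
sum(rep$monophyletic & !rep$trivial)   # a small minority of 10 labels
#> [1] 0
```

## Documentation

The vignette (`vignettes/supertype-dynamics.Rmd`) documents the model,
its assumptions, the calibration of the recognition kernel, what the
synthetic generators do and do not emulate, and known limitations.
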