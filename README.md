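# dispersim

**Marker-panel power analysis for genetic disperser detection.**

Ecologists routinely identify first-generation dispersers — individuals
sampled away from their natal population — with genetic assignment tests on
microsatellite panels. Most studies use around ten loci and never ask
whether that panel can actually detect dispersal in their system.
`dispersim` implements **Simulated Disperser Analysis (SDA)**: artificially
"move" individuals between your sampled populations by relabelling them,
re-run migrant detection over nested, information-ranked subsets of loci,
and read off how many markers your system needs before dispersers are
reliably recovered. It is aimed at population and landscape geneticists
designing or validating marker panels for contemporary dispersal studies.

## What it computes

**Assignment likelihood.** For a diploid genotype at a locus with global
allele inventory of size *k* and candidate-population allele counts
*n₁,…,n_k* (total *n*), the partial-Bayesian posterior-predictive
probability (Dirichlet prior αᵢ = 1/k) is

    P(ij) = 2 (nᵢ + 1/k)(nⱼ + 1/k) / ((n+1)(n+2))     i ≠ j
    P(ii) = (nᵢ + 1/k)(nᵢ + 1 + 1/k) / ((n+1)(n+2))

multiplied over called loci. Detection scores each individual with
*L_h / L_max* (home likelihood over the maximum across sampled
populations) against a Monte Carlo null of genotypes simulated from the
home population's frequencies; individuals with p < 0.01 (default) are
flagged and assigned to the maximum-likelihood source.

**Marker statistics.** Polymorphic information content
(PIC = 1 − Σpᵢ² − Σᵢ<ⱼ 2pᵢ²pⱼ²) for locus ranking, pairwise
Weir–Cockerham θ (F_ST), Shannon mutual information *I* (nats), and Monte
Carlo exact Hardy–Weinberg screening with Bonferroni correction.

**The SDA grid.** One candidate per population, all k^k placement
treatments (27 for three populations), 2L − 1 nested PIC-ranked panels
(57 for 29 loci), each cell classified as correct resident / correct
disperser / false positive / false negative / wrong source, plus minimal
panel sizes, a worst-case single-scenario shortcut, outcome heatmaps, and
logistic (optionally mixed) power models with Nakagawa–Schielzeth R².

**Synthetic ground truth.** A Balding–Nichols generator with plantable
true dispersers, including a preset shaped like a three-population,
29-locus starling panel with pairwise θ spanning ~0.026–0.08.

## Worked example

```r
library(dispersim)

sim <- simulate_starling_panel(seed = 42)
sim$table
#> genotype_table: 94 individuals, 29 loci, 3 populations
#>   populations: P1 (n=32), P2 (n=32), P3 (n=30)
#>   missing genotypes: 2.1%

pairwise_differentiation(sim$table)
#>   popA popB  theta_fst mutual_information
#> 1   P1   P2 0.07509392         0.14342845
#> 2   P1   P3 0.07496538         0.15432173
#> 3   P2   P3 0.02165306         0.06071683
```

P2 and P3 are the weakly differentiated pair (θ ≈ 0.022); P1 is distinct
(θ ≈ 0.075). No one is flagged in the unmodified data, so every
individual is eligible to serve as a simulated disperser:

```r
cfg <- assignment_config(alpha = 0.01, n_simulated = 1000, seed = 42)
baseline <- detect_migrants(sim$table, cfg)
sum(baseline$flagged_disperser)
#> [1] 0

cand <- select_candidates(sim$table, baseline, seed = 42)
plans <- enumerate_treatments(cand, populations(sim$table))
panels <- prefix_series(rank_loci(locus_stats(sim$table), "highest_first"))
length(plans); length(panels)
#> [1] 27
#> [1] 57

grid <- run_grid(sim$table, cand, plans, panels,
                 assignment_config(alpha = 0.01, n_simulated = 500, seed = 42))
minimal_panel(grid)
#>   disperser     direction minimal_size
#> 1    ind001 highest_first           14
#> 2    ind052 highest_first           15
#> 3    ind090 highest_first          Inf
#> 4    ind001  lowest_first           15
#> 5    ind052  lowest_first           28
#> 6    ind090  lowest_first          Inf
```

Reading: candidate `ind001` is classified correctly in **every** treatment
once 14 or more of the highest-PIC loci are used (15 when growing the
panel lowest-PIC-first); `ind090` — sampled in one of the two similar
populations — is never reliably recovered with the 29 loci available
(`Inf`), the kind of individual-level failure this analysis is designed to
expose. Overall, 72.9% of highest-PIC cells versus 63.1% of lowest-PIC
cells are correct, and `plot_sda_heatmap(grid)` shows exactly where
detection breaks down.

A command-line front end covering the same workflow (plus a `simulate`
subcommand) ships in `inst/scripts/sda-validate.R`:

```sh
Rscript inst/scripts/sda-validate.R validate-panel \
  --input mydata.gen --alpha 0.01 --nsim 10000 --seed 1 \
  --worst-case-only --out sda-out
```

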