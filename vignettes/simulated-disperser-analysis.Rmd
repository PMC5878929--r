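---
title: "Simulated Disperser Analysis: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated Disperser Analysis: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dispersim)
```

## The problem

Genetic assignment tests are widely used to identify first-generation
dispersers: individuals sampled in one population whose multi-locus genotype
is more probable under another population's allele frequencies. Most
empirical studies run such tests with whatever marker panel they have —
typically around ten microsatellites — without asking whether that panel has
the power to detect dispersal *in their system*. Simulated Disperser
Analysis (SDA) answers that question with the data alone: pick an
individual, relabel it into another population as if it had dispersed,
re-run detection over nested subsets of loci, and find the panel size at
which the artificial disperser stops being recovered.

`dispersim` implements the whole procedure: the assignment statistic and
its Monte Carlo null, the per-locus information statistics used to rank
markers, the treatment-by-panel grid, a generative simulator for testing,
and logistic power summaries.

## The assignment model

For an individual genotyped at loci $l = 1 \dots L$ and a candidate
population with observed allele counts $n_1, \dots, n_k$ (total $n$) at a
locus with $k$ distinct alleles observed *across all populations pooled*,
the partial-Bayesian (posterior-predictive) genotype probability places a
Dirichlet prior of total mass 1 on the allele frequencies
($\alpha_i = 1/k$):

$$P(ij) = \frac{2\,(n_i + 1/k)(n_j + 1/k)}{(n+1)(n+2)}, \qquad
  P(ii) = \frac{(n_i + 1/k)(n_i + 1 + 1/k)}{(n+1)(n+2)}.$$

The multi-locus likelihood is the product over called loci (missing loci
are skipped); alleles unseen in the candidate population retain prior
mass, so likelihoods are always finite. These probabilities sum to one
over all genotypes constructible from the inventory — a property the test
suite checks by enumeration.

Detection uses the ratio $L_h / L_{\max}$: the likelihood in the
population where the individual is labelled (home) over the maximum
across all sampled populations. Its null distribution is obtained by
simulating genotypes from the home population's observed frequencies (two
independent allele draws per locus — Hardy–Weinberg and linkage
equilibrium assumed) and scoring them identically. The Monte Carlo
p-value uses the $(r+1)/(N+1)$ estimator, so it can never be exactly
zero; an individual is flagged as a putative disperser when
$p < \alpha$ (default $\alpha = 0.01$, null size $N = 10{,}000$).

### Calibration of the two statistics

$L_h/L_{\max}$ equals 1 whenever home is the maximum-likelihood
population, which for genuine residents is the typical case. The
statistic therefore has a large atom at its upper bound and its p-values
are *conservative*: a resident population yields an empirical type-I rate
at or below $\alpha$, with a p-value distribution that is far from
uniform (most mass at $p = 1$). The alternative `statistic = "Lh"`
(the home likelihood alone) is continuous, and its p-values are uniform
under the null — the calibration checks in the test suite use it for the
uniformity property and the ratio statistic for the type-I bound. For
actual disperser detection with all candidate sources sampled the ratio
is the better-powered criterion and remains the default.

### Leave-one-out

By default the focal individual's own alleles stay in its home-population
counts (`leave_one_out = FALSE`), matching common migrant-detection
practice. Removing them (`leave_one_out = TRUE`) makes a resident's home
likelihood systematically smaller and, at sample sizes near 30, visibly
shifts p-values — with the simulated null drawn from the full counts it
overshoots and becomes anticonservative. The flag exists because the
choice matters; the default keeps observed and simulated genotypes on the
same footing.

## Marker statistics

* **PIC** (polymorphic information content),
  $1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2$, computed from allele
  frequencies pooled over all individuals. Pooling (rather than averaging
  per-population values) is a deliberate choice: locus ranking drives
  panel construction globally, not per population.
* **Weir–Cockerham $\theta$** for pairwise $F_{ST}$, variance components
  summed over alleles and loci. It is a method-of-moments estimator and
  may be slightly negative for undifferentiated pairs; that is expected
  behaviour, not an error. Other estimators (e.g. AMOVA-based
  $\Phi_{ST}$) agree to roughly two decimals on data of this shape.
* **Shannon mutual information $I$** between allele identity and
  population label, in natural-log units (nats), with population weights
  proportional to called allele counts and the multi-locus value taken as
  the unweighted mean over loci. $I = 0$ iff the two allele distributions
  coincide; two populations fixed for alternative alleles give
  $\ln 2 \approx 0.693$ per locus. Conventions differ across software in
  log base and weighting; these choices are stated so results are
  comparable.
* **Hardy–Weinberg screening** by a Monte Carlo conditional exact test:
  the probability of the genotype array given its allele counts is
  compared against random re-pairings of the observed alleles. The
  screening report applies Bonferroni correction across all
  (population, locus) tests and flags loci departing in two or more
  populations — flagged loci are candidates for exclusion, but removal is
  left to the user.

## The SDA engine

One candidate disperser per population is drawn at random from the
individuals whose baseline membership p-value is at least 0.05 —
individuals below that threshold may be real dispersers and are excluded
from candidacy (the threshold is a parameter). With $k$ populations, all
$k^k$ placement functions are enumerated as treatments (27 for three
populations), the identity placement included as treatment 0. Loci ranked
by PIC give $2L - 1$ nested panels: $L$ prefixes of the highest-first
ranking and $L - 1$ of the lowest-first ranking, the duplicate full panel
counted once (57 panels for 29 loci).

Every (treatment, panel) cell relabels the candidates, recomputes allele
counts — the prior dimension $k$ and the null distributions are
recomputed under the new labelling, exactly as a user re-running the
assignment software would experience — and classifies each candidate:

| placement | flagged | source call | outcome |
|---|---|---|---|
| home | no | — | `correct_resident` |
| home | yes | — | `false_positive` |
| away | no | — | `false_negative` |
| away | yes | true home | `correct_disperser` |
| away | yes | other | `wrong_source` |

"Correct" for a moved disperser requires *both* detection and correct
source assignment. The minimal panel size for a (disperser, direction)
pair is the smallest $m$ such that every panel of size $\ge m$ classifies
the disperser correctly in every treatment; if a larger panel ever fails,
the minimum moves past it, and `Inf` records that no size suffices within
the available loci.

The worst-case shortcut (`worst_case_plan`) condenses the grid into the
single most stringent scenario: each candidate is moved to the population
with the lowest pairwise $I$ from its home (lowest $\theta$ as fallback)
and panels are grown lowest-PIC-first. Ties in similarity break
lexicographically, with a message.

One global PIC ranking from the unmodified table is used for all
treatments; re-ranking after each relabelling would let the moved
individuals perturb the panel order and make directions incomparable
across treatments.

## The synthetic generator

`simulate_dataset` draws from a Balding–Nichols island model: ancestral
frequencies $p \sim \mathrm{Dirichlet}(c,\dots,c)$ over $k$ alleles
($k$ uniform on 2–20 by default, the span of typical microsatellite
panels), population frequencies
$\sim \mathrm{Dirichlet}(p\,(1-F)/F)$, genotypes as two independent
draws. $F$ is the expected divergence of each population from the
ancestral pool, and the realised pairwise Weir–Cockerham $\hat\theta$
between two populations recovers it closely (mean over 50 replicates
within a few percent of $F$ — a parameter-recovery test in the suite).
`plant_dispersers` appends individuals drawn from one population's
*latent* frequencies but labelled elsewhere: ground truth for power
estimation.

`simulate_starling_panel` is the default study-shaped preset: three
populations of 32, 32 and 30 individuals, 29 loci, 2% missingness, and a
hierarchical two-level structure (two populations diverging mildly from a
shared pool that is itself well separated from the third). The two levels
(`f_far = 0.068`, `f_near = 0.026`) were calibrated once, by replicate
simulation, so that mean pairwise $\hat\theta$ spans roughly 0.026
(the similar pair) to 0.08 (the distinct population) — the
weak-to-moderate structure regime in which panel power actually is in
question.

What the generator does **not** emulate: stepwise mutation (allele codes
are exchangeable labels; assignment mathematics only consumes
frequencies), linkage, null alleles, allelic dropout or scoring error
beyond uniform missingness, and within-population substructure. Passing
tests on synthetic data therefore certify the machinery and its
calibration under idealised sampling, not robustness to genotyping
artefacts.

## Numerical and reproducibility choices

* All likelihood work is on the log10 scale; panels are scored by summing
  precomputed per-locus log-likelihoods, so a 27-treatment × 57-panel
  grid costs seconds, not hours.
* Argmax ties in source assignment break toward the home population,
  then to the lowest population index (tolerance $10^{-12}$ on log10
  likelihoods).
* Every Monte Carlo draw derives a deterministic sub-seed from the master
  seed and a string key (population, treatment id, locus panel), so grid
  cells are reproducible independently of evaluation order, and one null
  distribution is shared by all individuals of a (population, panel,
  treatment) combination.
* A population with zero called alleles at a locus has that locus dropped
  from its simulation and scoring, with a message; a genotype with one
  unreadable allele is treated as fully missing (half-calls are not
  interpretable without an error model).
* The test suite and the acceptance script run at deliberately modest
  sizes — null distributions of 200–1,000 draws, 25–50 simulation
  replicates, around 500 synthetic residents for calibration checks —
  chosen so the full analysis regenerates in minutes while keeping Monte
  Carlo error well inside the asserted tolerances. Empirical studies
  should keep the 10,000-draw default.

## Known limitations

* Reported minimal panel sizes are conditional on the candidates drawn
  and on Monte Carlo noise in the p-values; at small null sizes the
  p-value granularity ($1/(N+1)$) can make the strict 100%-correct
  criterion unattainable, which surfaces honestly as `Inf`.
* The mixed-effects power model delegates to `lme4` when installed;
  without it the fit is fixed-effects only (with a message), which leaves
  the coefficient signs and monotonicity conclusions intact but changes
  their standard errors and the conditional $R^2$.
* Mutual information conventions (log base, weighting) vary between
  programs; comparisons with values computed elsewhere should check the
  conventions above before attributing discrepancies to the data.
* Exact correspondence with any particular assignment program's numbers
  is not guaranteed: undocumented implementation details (p-value
  convention, half-call handling, simulation scheme) differ between
  programs; the formulas implemented here are the openly published ones,
  verified against hand-computed oracles in the test suite.
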