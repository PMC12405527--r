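---
title: "Modelling transient mutator bursts in growing colonies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling transient mutator bursts in growing colonies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

A clonal yeast colony grows from a single cell to roughly 2^27 cells over
a few days. Along the way it accumulates mutations: large segmental
duplications ("D"), reciprocal translocations ("T"), and point mutations
such as CAN1 loss of function ("C"), each detectable with a selective
reporter and each with a measurable per-cell-per-division rate. If every
cell mutated at the same constant rate, double mutants (a cell carrying,
say, both D and C) would arise either *simultaneously* — both hits in one
division, with probability equal to the product of the two rates — or
*sequentially*, when a descendant of an existing single mutant picks up
the second hit in a later cell cycle. Observed double-mutant rates well in
excess of this constant-rate expectation are the signature of *transient
mutators*: subpopulations of genetically wild-type cells that pass through
a short-lived hypermutable state.

`mutburst` implements the full quantitative chain needed to make that
argument from fluctuation-assay count data and simulation: mutation-rate
estimation, a stochastic null model of mutation accumulation during colony
growth, a refined model with a transient mutator subpopulation, a sweep
constraining that subpopulation's size/strength/duration, and a binomial
model of genome-wide non-selected mutation burden.

## Fluctuation analysis

A fluctuation assay grows many parallel cultures and counts mutant
colonies on selective plates. Because a mutation arising early founds a
large clone, the counts are heavy-tailed ("jackpots"); the natural
parameter is `m`, the expected number of mutation *events* per culture,
and the per-cell-per-division rate is `m / Nt` with `Nt` the final number
of cells.

The mutant-count distribution is compound Poisson under the Lea–Coulson
formulation: events are Poisson(`m`) and each event founds a clone whose
final size `j` has probability `1/(j(j+1))`. `ld_pmf()` evaluates it with
the Panjer recursion, which for a plating fraction of 1 reduces *exactly*
to the Ma–Sandri–Sarkar recursion
`p0 = exp(-m)`, `p_n = (m/n) sum_{j<n} p_j/(n-j+1)`. Partial plating
(only a fraction ε of each culture on the selective plate) thins each
clone binomially; the per-event observed-count law is computed once per
dataset by iterated binomial convolution against the clone-size law and
fed to the same recursion. The ε = 1 reduction is asserted exactly in the
tests, and the ε < 1 distribution is validated against a Monte-Carlo
thinning oracle (Kolmogorov distance < 0.01 at `m = 2`, ε = 0.1).

`mle_rate()` maximizes the censored log-likelihood by bracketed search on
`log(m)` (relative tolerance 1e-7) and reports 95% profile-likelihood
intervals located by bisection to the `qchisq(0.95, 1)` deviance contour
(relative tolerance 1e-4). Two numerical choices matter:

* **Right-censoring of jackpots.** The recursion is O(cap^2), so counts at
  or above `cap = min(censor_limit, max(65, max(count) + 1))` contribute
  the tail mass `P(count >= cap)` instead of an exact term. The default
  `censor_limit` of 10^4 (4096 inside sweeps) keeps the bulk of every
  realistic count distribution exact — at the single-channel scale of this
  analysis (`m ~ 440`, counts in the thousands) a much smaller cap would
  censor essentially every culture and destroy the likelihood's curvature.
* **Log-scale recursion.** `exp(-m)` underflows for `m` beyond ~700, so
  the recursion runs rescaled with an accumulated log offset; likelihood
  evaluations remain finite for the strength-inflated channels visited by
  the sweep.

The boundary case of all-zero counts returns `m_hat = 0` with the
analytic interval `[0, qchisq(0.95,1)/(2n(1-r0))]`. `lr_test()` compares
two experiments through the standard 1-df likelihood-ratio statistic
against a common per-cell rate. Calibration is part of the test suite:
interval coverage on synthetic data sits in the 90–99% band and the
likelihood-ratio test's type-I error is ~5%.

## The colony growth models

`simulate_colonies()` propagates genotype-class *counts* (not individual
cells) one synchronous generation at a time: every cell produces one
daughter; daughters of wild-type mothers become single mutants with
probabilities `mu1(1-mu2)` and `mu2(1-mu1)` or simultaneous doubles with
probability `mu1*mu2` (one joint multinomial draw per class); daughters of
single mutants acquire the other mutation at its rate and found
*sequential* doubles. Mothers never mutate, nobody dies, nothing reverts,
and the population is exactly `2^g` at generation `g` — an invariant the
tests assert generation by generation. Count propagation is what makes
2^27-cell colonies tractable; a cell-by-cell simulator exists in the test
suite purely as an oracle, and the two agree in distribution at small
colony sizes (chi-square goodness of fit, p > 0.01).

The refined model adds one transient episode per colony, described by
`mutator_params(size, strength, duration)`: at an onset generation `g0`,
`size` cells (sampled across genotype classes in proportion to abundance,
by multivariate hypergeometric draws) move into a mutator cohort whose
daughters mutate at `strength`-fold rates for `duration` generations,
after which the cohort folds back into the basal population.

Three modelling choices were genuinely open:

* **Onset policy.** The episode's onset is only constrained by "cells are
  picked from the growing population". The default draws `g0` uniformly
  from `{ceiling(log2(size)), ..., G-1}` — the earliest generation whose
  population can supply the episode, up to the penultimate one. The policy
  is pluggable (`onset = "fixed"` pins `g0`), and the regime statistics
  below are sensitive to it; this is the model's single most consequential
  free choice.
* **Inheritance.** Mutator state is inherited by daughters during the
  episode and reverts synchronously after `duration` generations, so that
  size and duration act independently (an episode of size S and duration d
  exposes `S(2^d - 1)` daughter divisions to the elevated rates).
* **Admissibility.** After strength multiplication the per-division
  probabilities must satisfy `F*mu1 + F*mu2 + F^2*mu1*mu2 <= 1`;
  configurations outside it are rejected (the largest strength swept here,
  10^4 over 3.3e-6, is safely admissible).

`estimate_model_rates()` closes the loop with the experiment: each
realization's final counts of channel-bearing cells are treated as one
fluctuation culture with `Nt = 2^G`, and the same MLE machinery estimates
"theoretical" single and double rates directly comparable with measured
ones. Note one deliberate asymmetry this creates: the estimator assumes
Lea–Coulson clone sizes while the simulator doubles discretely, so
simulated single-channel estimates at the basal rates sit 10–20% below
the generating values (the estimators used on real data show comparable
dialect-dependent spread at high rates). All compatibility judgements in
the sweep are made in this common estimator scale.

## The parameter sweep and accumulation regimes

`run_sweep()` explores a logarithmic grid over size, strength and
duration (defaults mirror the explored ranges: sizes 10–10^4 in the
acceptance analysis, strengths 10^2–10^4 in half-decade steps, durations 1
and 5, at least 1000 realizations per point). A point is *accepted*
("green") when

* the observed double rate lies inside the point's simulated double-rate
  95% profile interval, and
* both simulated single-rate point estimates fall inside the observed
  single-rate bands.

The shipped default band is a factor of two around each observed single
rate. This is the package's own stand-in for per-experiment confidence
intervals, which require the raw culture counts; it is deliberately
conservative, and everything downstream of the green set inherits its
width. `regime_summary()` then pools the accepted points' realizations:
the simultaneous share of double-founding events, onset-generation means
for realizations yielding sequential vs simultaneous doubles, the
double-free fraction, and the single-mutant scatter.

Under the study conditions (rates 3.3e-6 and 1.6e-7, G = 27), the null
model run at 50,000 realizations gives a sequential share of double
mutants around 95% and a theoretical DC double rate roughly 13–17-fold
below the observed 1.8e-10 — both recomputed from scratch by
`scripts/acceptance.R` and the acceptance tests. Accepted sweep points
show the expected structure: compatible strengths fall with size, episodes
yielding sequential doubles start early (mean onset near generation 9–11)
while simultaneous-yielding episodes start late (near 17–19), and ~98% of
realizations end double-free.

## Mutation burden

`burst_model()` treats non-selected substitutions as
`Binomial(L*G, p)` — every genomic site is a trial at every division —
with defaults L = 12 Mb, p = 3.3e-10 substitutions/site/generation,
G = 27. `tail_prob()` evaluates survival probabilities through the
regularized incomplete beta function, which is stable in the extreme tail
(P(>= 11) ~ 5e-19; subtracting CDFs near 1 would return garbage there).
`strain_excess_test()` compares the observed number of strains carrying
extra mutations with this expectation through an exact one-sided binomial
tail.

## What the synthetic data do and do not show

`make_fluctuation_table()` and `make_double_mutant_experiment()` generate
fluctuation tables whose every culture is a simulated colony, with
optional binomial plating thinning and an optional embedded episode; all
channels derive from the *same* realizations, preserving the
within-colony correlation that gives the double-mutant excess its
meaning. Ground-truth manifests (JSON) make every artifact regenerable
bit for bit.

Passing recovery tests on these tables shows the estimation chain is
self-consistent under the model's own assumptions — synchronous divisions,
no death, no fitness differences, rates constant outside the episode, one
episode per colony. Real colonies violate several of these (asynchronous
growth, spatial structure, stationary-phase physiology), so agreement
here validates the computational chain, not the biology.

## Known limitations

* Regime statistics depend on the unspecified onset-generation law; the
  uniform default reproduces the early-vs-late onset separation but any
  quantity tied to the onset distribution carries this assumption.
* The green criterion inherits the ±2-fold default bands. Tighter,
  data-derived bands shrink the accepted set at its large-size edge, where
  simulated simultaneous fractions are highest; with the default bands an
  occasional large-size point is accepted and the maximum simultaneous
  share can exceed 12.5% depending on the seed.
* The share of colonies with more channel-1 than channel-2 single mutants
  is ~99% under this model at the study rates: with a 20.6-fold rate
  ratio and episodes boosting both channels equally, channel-2 essentially
  never overtakes channel-1. Reported values nearer 90% would require a
  mechanism (per-channel episodes, a different onset law) that the model
  deliberately does not include.
* One episode per realization, two mutation channels, no phenotypic lag,
  no death, no differential fitness, no Bayesian estimation — all out of
  scope by design.

## Problem sizes

The acceptance analysis uses 50,000 null realizations for the origin
regime and theoretical double rate, and a 40-point sweep at 1000
realizations per point; the test suite uses the same sweep plus smaller
calibration studies (200-dataset coverage, 100-pair likelihood-ratio
calibration, 2000-seed oracle comparisons at G <= 10). These sizes hold
Monte-Carlo error on every reported percentage to about one point.
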