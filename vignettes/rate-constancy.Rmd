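---
title: "Testing rate constancy before borrowing a molecular clock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing rate constancy before borrowing a molecular clock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratecon)
```

## The problem

Secondary ("universal") substitution-rate calibrations are routinely borrowed
from one taxonomic group to date divergences in another — for example,
applying insect mitochondrial COI rates to springtails. The borrowed rate is
only meaningful if the focal group's substitution rate is close to the rate
of the group the calibration came from, i.e. if rate constancy holds across
the clade. `ratecon` implements a self-contained workflow for checking that
assumption on a protein-coding alignment:

1. **Saturation screening.** Substitution saturation erodes phylogenetic
   signal at deep timescales, especially at third codon positions. Two
   diagnostics are run: a regression (through the origin) of uncorrected
   p-distances on model-corrected distances per codon partition, and an
   entropy-based index of substitution saturation (Iss) compared against
   simulation-derived critical values.
2. **Relative-rate estimation.** A Bayesian relaxed-clock analysis on a
   *fixed* topology (taken from a trusted phylogenomic study) with the mean
   branch rate anchored to 1 substitution/site/time, so every branch rate is
   a dimensionless multiple of the tree-wide average.
3. **Rate-constancy calls.** For each named group, the time-weighted mean of
   its within-clade (crown) branch rates is summarised by its posterior mean
   and 95% highest posterior density (HPD) interval. A group *deviates from
   the mean rate* if its HPD excludes 1, and *differs from the focal group*
   if the two HPD intervals are disjoint. A secondary calibration is deemed
   appropriate for the focal group iff its HPD includes 1.

## The model

Sites evolve independently under GTR+Gamma(4)+I. The six exchangeabilities
(GT fixed at 1), stationary frequencies, gamma shape and proportion of
invariant sites are all sampled. The rate matrix is normalised to one
expected substitution per unit branch length at stationarity; discrete gamma
categories use the standard mean-per-category discretisation. Symbols other
than A/C/G/T are treated as missing data. The likelihood is computed by
Felsenstein's pruning algorithm over compressed site patterns with per-node
rescaling (implemented in C++; verified in the test suite against exhaustive
ancestral-state enumeration on 4-5 taxon trees to 1e-8, against a
two-sequence Jukes-Cantor closed form, and against an independent
implementation).

### Tree prior

Node heights carry a *ranked pure-birth* prior: the n-1 internal node
heights are the descending order statistics of i.i.d. Exponential(birth
rate) draws, assigned to nodes by a uniformly chosen ranking compatible with
the topology. For a fixed topology the density is

```
prod_v s_v  *  prod_i lambda exp(-lambda h_i)
```

over the region where every parent is above its children, where `s_v` counts
the internal nodes in the subtree of `v` (a hook-length normalisation; the
tests verify it against brute-force enumeration of linear extensions and by
numerical quadrature). For two tips this reduces to the classic exponential
root-age law. `simulate_yule_tree()` samples from exactly this distribution,
so the prior-recovery check (a likelihood-free MCMC run compared against
direct prior simulation by a Kolmogorov-Smirnov test) exercises both
directions of the same object. The birth rate itself gets a log-uniform
prior on [1e-6, 1e3].

### Clock model and identifiability

The clock is an uncorrelated lognormal with real-space mean fixed to exactly
1 (`meanlog = -ucld_stdev^2/2`), and it is *quantile-discretised*: with E
branches, branch e carries rate `qlnorm((c_e - 0.5)/E)` where `(c_1..c_E)`
is a permutation of 1..E sampled by category swaps, and the spread
`ucld_stdev` has an Exponential(mean 1/3) prior. The realised rates are
therefore always a stratified sample of the lognormal with the current
spread.

This discretisation is a deliberate design choice, not a convenience. With
continuous i.i.d. lognormal rates the posterior can absorb a clade-specific
rate acceleration entirely: the clade's crown node heights stretch (the
likelihood constrains only rate x time per branch), and the residual
deviation is spread thinly over many branches, which the quadratic lognormal
log-density always prefers to a few large deviations. In experiments with a
16-taxon tree and a 3x accelerated clade, the continuous-rate posterior
converged to clade rates near 1 with stretched crowns — the acceleration was
invisible no matter how long the chain ran. Under the quantile clock that
escape is blocked: deflating many branch rates requires a large spread,
which in turn forces real dispersion onto branches whose data are
clock-like, and the likelihood refuses. The cost is granularity: with E
branches the largest representable rate is the top lognormal quantile, so a
two-point truth ("most branches at 1, a few at 3") is recovered with
attenuated magnitude (the flagged clade's posterior mean is typically
1.3-1.8 rather than 3), while the *calls* — HPD excludes 1, disjoint from
the focal clade — remain correct. Magnitudes become accurate as taxon
sampling grows.

A second geometric requirement is worth knowing about: a rate multiplier on
a clade is identifiable only when the clade's crown cannot stretch to absorb
it — that is, when the crown age is a substantial fraction of its stem
parent's age and the backbone above is pinned by other densely sampled
groups. This is exactly the situation of named orders packed under a shallow
backbone in the empirical setting the package targets. The packaged study
topology `deep_crown_tree()` (16 taxa, four named clades with crown ages
0.4-1.0 on a root of 1.5) reproduces that geometry; on trees whose clades
are young shallow crowns (e.g. small random Yule trees), accelerations are
genuinely unidentifiable under any relaxed clock of this family, because
stretching the crown explains the data at no likelihood cost and negligible
prior cost.

### Moves and tuning

Standard Metropolis-Hastings kernels: category swaps (mostly between
adjacent quantiles), uniform node-height slides within their bracketing
nodes, scale moves for the root, subtree heights (a coherent crown
stretch/shrink, which is the slow direction of the posterior), the whole
height vector, the clock spread, gamma shape, exchangeabilities and birth
rate, a reflected random walk for the invariant proportion, and a
delta-exchange for frequencies. Scale and window sizes adapt towards ~30%
acceptance during burn-in only, so the post-burn-in chain is a fixed-kernel
sampler. Chains are initialised from parsimony branch lengths (categories
assigned by the rank of crude per-branch rates; heights scaled so the mean
rate starts at 1) and are bit-reproducible under a fixed seed.

## Saturation diagnostics

**Regression.** For each codon partition ({1}, {2}, {3}, {1,2}, {1,2,3}),
uncorrected p-distances (pairwise deletion) are regressed through the origin
on model-corrected distances; the GTR model is estimated once on the full
alignment (frequencies empirical, exchangeabilities maximised on a
neighbour-joining guide tree) and reused for every pair, and each pairwise
distance is the branch length maximising the two-sequence likelihood
(bounded 1-D optimisation, capped at a configurable maximum of 10 with a
saturation flag). The uncentred R2 (`1 - sum((y - bx)^2)/sum(y^2)`) is the
only definition consistent with a no-intercept fit. Codon position 3 is
recommended for inclusion iff R2({1,2,3}) >= R2({1,2}) - threshold (default
0.01). Note that the combined criterion is deliberately conservative and, in
our experiments, almost never excludes codon 3: when positions 1-2 remain
informative the combined corrected distance plateaus together with the
combined uncorrected distance, so the combined R2 stays high even when the
codon-3-only R2 has collapsed — real COI datasets across deep arthropod
divergences behave the same way. The per-partition R2 values are the
informative diagnostic; the threshold is exposed for stricter policies.

**Iss.** The index of substitution saturation for an alignment of n
sequences is the mean per-site entropy over the variable fraction of sites
divided by `H_FSS`, the *expected* entropy of a fully saturated column,
i.e. of n i.i.d. draws from the empirical base frequencies (computed exactly
from binomial marginals). We use the expected-entropy definition rather than
the population entropy `-sum f log2 f`: only under it does a fully
randomised alignment give Iss ~ 1 (the defining calibration point of the
index). One consequence worth noting is that a contrived alignment whose
every column contains each base exactly once has Iss > 1, since its columns
are *more* even than saturation produces at small n. Invariant sites are
handled by dividing the total column entropy by
`sites_used = round((1 - p_inv) * n_sites)`; the t-test of observed Iss
against the critical value then has `sites_used - 1` degrees of freedom
(1491 sites with p_inv = 0.21 give df = 1177). The critical value Iss.c is
estimated by simulation: alignments are evolved on balanced ("sym") or
caterpillar ("asym") ultrametric topologies over a grid of depths,
neighbour-joining recovery of the true topology is measured, and the mean
observed Iss is interpolated at the depth where recovery falls to 0.95
(deepest grid point still meeting the threshold, which is robust to noisy
recovery estimates at shallow depths; boundary cases return the boundary Iss
with a warning). Whether the alignment's own p_inv comes from a fixed value
or the empirical proportion of constant columns is configurable; the
pipeline defaults to the empirical estimate to avoid making the saturation
gate depend on the MCMC stage.

## The synthetic-data generator

`simulate_dataset()` produces alignments with known truth: a Yule tree
(`simulate_yule_tree()`), branch rates from the mean-1 lognormal with
optional per-clade multipliers applied to crown branches only (matching the
within-clade summary rule used at inference time), and GTR+Gamma+I site
evolution with codon-position rate multipliers. The defaults emulate a
COI-like single-gene study: 16 taxa, AT-rich transition-biased
exchangeabilities (AG = 4, CT = 7), gamma shape 0.5, 20% invariant sites,
and codon-position multipliers (0.45, 0.15, 2.40) that concentrate change on
position 3 strongly enough to saturate it on deep trees. What the generator
does *not* emulate: alignment error, indels, codon (dN/dS) selection,
among-lineage base-composition drift, and heterotachy — so passing recovery
tests demonstrate correctness of the inference machinery under its own
model, not robustness to real-data violations of it.

The recovery experiments in the test suite run at desk scale: 900-1500
sites and 2.5-4 x 10^4 MCMC proposals per replicate, sizes chosen so a full
battery of 20 replicates per condition completes in minutes on one core
while keeping clade-rate Monte-Carlo error well inside the decision
margins. Production analyses should use the package defaults (5 x 10^5
proposals) or more, and check that all reported ESS values exceed 200.

## Numerical choices

- Transition probabilities come from the symmetrised eigendecomposition of
  the GTR generator; tiny negative entries are clamped to zero and rows
  renormalised.
- Partial likelihoods are rescaled per node and pattern; the invariant-site
  class is combined on the log scale.
- Pairwise distance optimisation uses `optimize()` with tolerance 1e-9 on
  [0, 10]; a pair whose optimum sits at the cap is flagged saturated.
- HPD intervals are the exact shortest window over the sorted samples
  (`ceiling(prob * N)` of them); ESS uses initial-positive-sequence
  truncation of the empirical autocorrelations, with the convention ESS = N
  for a constant series.
- The MCC tree maximises the product of clade posterior frequencies and is
  annotated with per-clade median heights and median stem rates; when
  independently computed medians would invert a parent below a child, the
  parent is nudged just above it.
- Degenerate inputs error early with stage-tagged messages (ragged
  alignments, duplicate labels, polytomies, invariant alignments, clades
  that are not monophyletic).

## Known limitations

- Fully fixed topology: groups left unresolved by the constraint source
  cannot be re-estimated here, and clades non-monophyletic on the fixed tree
  are skipped (and counted) rather than imputed.
- Quantile-clock granularity attenuates the *magnitude* of extreme clade
  rates at small taxon counts (calls are unaffected; see above).
- Single-partition model: no codon models, no among-partition model
  averaging; the GTR+Gamma+I envelope stands in for substitution-model
  averaging.
- The Iss critical values are simulation-based with a configurable 0.95
  neighbour-joining reliability threshold; they are not intended to
  numerically replicate any external implementation's lookup tables.
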