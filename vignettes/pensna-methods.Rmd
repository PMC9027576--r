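---
title: "Quantitative genetics of pen-level aggression networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative genetics of pen-level aggression networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pensna)
```

## The scientific problem

When unacquainted pigs are mixed into a pen they fight to establish a
dominance hierarchy, injuring each other and depressing welfare and
performance. Each animal's role in that aggression can be summarised by
node-level statistics of the pen's *aggression network*: the undirected,
unweighted graph whose vertices are the 15 pen mates and whose edges record
at least one fight or bullying interaction within a dyad during the 24 h
after mixing. `pensna` implements the full quantitative-genetic analysis of
these network traits: it computes the traits, estimates their heritabilities
and genetic correlations with skin-lesion counts under Bayesian animal
models, and predicts the correlated response in lesion traits when animals
are truncation-selected on network-trait breeding values.

Because the motivating dataset (1,146 phenotyped pigs in 78 pens, a
two-generation pedigree of ~2,400 animals) is not public, the package ships
a first-class synthetic-data generator that reproduces the study's
*structure* — pedigree, pen composition, trait architecture — so that every
stage of the pipeline can be exercised and validated end to end. All
empirical statements below are about what the package's tests and
acceptance script themselves compute on such synthetic data.

## Network traits

Per pen, fight and bullying records are combined ("an edge is an edge"),
direction and duration deliberately discarded. Seven node traits are
computed per animal:

* **degree centrality** `k_i / (n-1)` (raw degree also reported);
* **betweenness centrality**, the fraction of geodesics between other pairs
  passing through the node, normalised by `(n-1)(n-2)/2`;
* **closeness centrality** with the reachable-set convention for
  disconnected graphs: `(r/D)(r/(n-1))` for `r` reachable others at total
  distance `D`; isolates score 0;
* **eigenvector centrality**: Perron vector of the adjacency matrix of the
  largest connected component, rescaled to maximum 1 (a unit-L2 option is
  provided); vertices outside that component score 0; an edgeless pen
  returns all zeros with a warning;
* **local clustering coefficient** `2T_i / (k_i (k_i - 1))`, set to 0 for
  degree < 2 so every animal stays phenotyped;
* **clique membership**: indicator of belonging to at least one maximum
  clique (exact enumeration; pens have only 15 nodes);
* **categorical betweenness**: animals at or above the 75th percentile of
  the *population-wide* betweenness distribution are "high" (ties at the
  cut are high; a per-pen variant would be a trivial change but the
  population-wide reading matches the trait's definition).

Centralities are delegated to igraph; the test suite checks them against
independent brute-force oracles (Floyd–Warshall distances with path-count
dynamic programming, a shifted power iteration, triangle counting, subset
enumeration) on hundreds of random graphs, exactly for the combinatorial
quantities and to 1e-8 for the eigenvector.

The continuous traits are strongly right-skewed, so the modelling scale is
their square root; lesion counts enter as `log(count + 1)`, with the 24 h
counts first reduced by the pre-mixing count (negative differences clamped
to zero with a warning — the raw records cannot distinguish healed from
miscounted lesions).

## The animal model

For each trait (or pair of traits) the model is

$$
y = Xb + Za + Wc + e,\qquad
a \sim N(0,\, A \otimes G_0),\quad
c \sim N(0,\, I \otimes C_0),\quad
e \sim N(0,\, I \otimes R_0),
$$

with fixed effects line (2 levels), sex (3 levels: female, male, castrated),
batch (14 levels) and centred weight-at-mixing as covariate; `a` is the
additive genetic effect of every pedigree animal (non-phenotyped ancestors
included through the relationship structure), `c` the common environmental
pen effect, and `A` the numerator relationship matrix. `A` is built by the
tabular method with inbreeding tracked by the Meuwissen–Luo recursion, and
its sparse inverse directly by Henderson's rules; both constructions are
cross-validated against a top-down kinship recursion.

### Gibbs sampler

Posteriors are sampled by single-site Gibbs sampling in compiled code, the
scheme long used by this model family's standard software. Location effects
are updated one scalar at a time from their normal full conditionals,
maintaining the residual vector and the product `u = A^{-1}a` incrementally
(with a periodic exact refresh to stop floating-point drift), so one sweep
costs O(records + nonzeros of `A^{-1}`). A blockwise update via a sparse
factorisation was considered and rejected: at this problem size
(≈2,000 records, ≈2,500 pedigree animals) the single-site sweep is an order
of magnitude cheaper per iteration and the chain lengths used here give
ample effective sample sizes, which matters because the validation suite
runs dozens of independent fits.

Covariance components get flat (improper inverse-Wishart, `nu = -(k+1)`,
zero scale) priors for all-linear models, giving inverse-Wishart full
conditionals with scales `a'A^{-1}a`, `c'c` and `e'e`. Models containing a
threshold trait default to a proper weakly informative prior
(`nu = k+1`, scale `0.1 I`): binary records constrain the liability-scale
variances only weakly and under the fully flat prior the genetic-variance
chain can drift towards an improper mode (observed directly as a
monotonically climbing 200k-iteration trace). Either prior can be forced
via `mcmc_settings(prior = )`. Draws use the Bartlett decomposition; near-singular scale
matrices are jittered towards SPD (exercised by the degenerate
duplicated-trait test).

### Threshold traits

Binary traits (categorical betweenness, clique membership) follow the
threshold liability model: an unobserved normal liability determines the
category by its sign, the threshold is fixed at 0 and the liability-scale
residual variance at 1. Liabilities are redrawn each iteration from
truncated normal full conditionals by inversion. The residual step depends
on the model:

* univariate threshold — no residual draw (variance fixed at 1);
* linear–threshold — the restricted residual covariance is sampled through
  the regression decomposition `e_lin | e_thr ~ N(beta e_thr, psi)`, whose
  normal / scaled-inverse-chi-square full conditionals keep the unit
  restriction exact;
* threshold–threshold (experimental) — the residual correlation is updated
  by a random-walk Metropolis step on (−1, 1).

An earlier draw-and-rescale implementation was measurably *not* invariant
under the flat prior (the genetic variance decayed geometrically) and was
replaced by the schemes above; the recovery experiments below would catch
any such defect.

### Chain protocol and summaries

The full-scale protocol for production analyses of this model family is
1,000,000 iterations, 100,000 burn-in, thinning 20. The package's default —
used throughout the tests and the acceptance script — is the reduced
protocol 50,000 / 5,000 / 10 (20,000 / 2,000 / 10 for the EBV-ranking fits
of the selection study, where only the ordering of posterior-mean breeding
values matters and variance components are not reported). These sizes were
chosen once, as the smallest runs at which the recovery experiments sit
comfortably inside their tolerances.

`summarize_posterior()` turns the stored draws into derived chains —
heritability `h2 = s2_a / (s2_a + s2_c + s2_e)` (liability scale for
threshold traits), pen fraction `c2`, phenotypic variance, and genetic
correlation `rg = G_12 / sqrt(G_11 G_22)` — and reports posterior mean, SD
and the HPD95% as the shortest contiguous window over the sorted draws
(ties towards the smallest lower bound). EBVs are posterior means of `a`.
Convergence can be checked with the Raftery–Lewis run-length diagnostic and
effective sample size (via coda).

## Selection response

EBVs are standardised to z-scores (sample SD, divisor `n−1`; the population
divisor is selectable and immaterial at n ≈ 1,100). Truncation selection
takes the `floor(fraction n)` animals with the lowest criterion — a
single-trait EBV or the equal-weight eigenvector–clustering index — and the
correlated response is reported as mean ± SE of each lesion-trait EBV (or
phenotype) in the selected group, next to the population mean. SEs are over
selected animals (the alternative, over posterior draws, is not what the
reported bar charts suggest). Pen-level selection ranks pens by the per-pen
mean or SD (diversity) of the criterion and reports the response over all
animals in the lowest 20% of pens. Ties are broken by stable input order;
EBVs come from univariate fits, since the selection procedure consumes
per-trait EBVs independently.

## The synthetic-data generator

The generator reproduces the study conditions as defaults:

* **pedigree**: 82 founder sires and 217 founder dams, one mate per dam,
  ~10 offspring per dam in litters of up to 10 — ≈2,470 animals in total,
  of which the penned subset (78 pens × 15 = 1,170) is phenotyped. (The
  published total of 2,427 with 1,146 phenotyped implies an offspring
  generation much larger than the phenotyped subset; the generator keeps
  that structure rather than forcing the exact counts.)
* **pens**: 15 animals of one sex and line, exactly 3 from each of 5
  litters, filled greedily from the litters with most unused animals;
  batches round-robin over 14; weight-at-mixing ~ N(30, 2.5²) kg,
  matching ~71-day-old pigs.
* **breeding values**: founders iid `N(0, G0)`, offspring = parent average
  plus Mendelian sampling with variance `(1/2 − (F_s+F_d)/4) G0`; replicate
  covariances converge to `A ⊗ G0` (verified in tests on 10,000 simulated
  families).
* **phenotypes**: emitted directly on the transformed analysis scale —
  fixed effects + breeding value + per-pen `N(0, C0)` effect + residual.
  Raw lesion *counts* (Poisson-type) are only needed to exercise the
  transforms module and are generated separately in its tests.
* **networks**: the aggression graph is generated from a latent
  aggressiveness trait `l` (itself a simulated phenotype, h² = 0.3): each
  within-pen dyad gets a fight edge with probability
  `plogis(-1.0 + 0.8 (l_i + l_j))` and a bullying edge with
  `plogis(-2.0 + 0.5 (l_i + l_j))`. The study gives no generative network
  model; these defaults were chosen once so that mean degree lands near the
  5–6 partners the reported degree distribution implies.
* **the "paper-like" preset** (`paperlike_parameters()`): 8 traits —
  eigenvector centrality, clustering coefficient and six lesion traits
  (3 regions × 2 time points) — with h², c², phenotypic variances and
  genetic correlations set to the published posterior means (e.g.
  h² = 0.22 for eigenvector centrality, rg = −0.95 between eigenvector and
  clustering, +0.54 with anterior 24 h lesions). Quantities the study did
  not publish (lesion h²/c²/Vp, lesion–lesion correlations) use plausible
  literature-range values: h² 0.15–0.25, c² 0.10, Vp from the reported
  phenotypic SDs, rg 0.3 within / 0.1 across time points. The assembled
  correlation matrix is indefinite (smallest eigenvalue ≈ −0.31, an
  unsurprising consequence of combining pairwise posterior means estimated
  in separate bivariate runs) and is projected to the nearest PSD
  correlation matrix; the projection preserves every sign and most
  magnitudes (the largest change, eigenvector–clustering, moves from −0.95
  to ≈ −0.80).

What the generator deliberately does **not** emulate: temporal fight
dynamics and durations, selection over generations, social (indirect)
genetic effects, non-normal residuals, missing-data patterns of real
recording, and the exact normalisation of the original network software
(the published trait ranges cannot be reconciled with any single standard
normalisation; no attempt is made to force a match). Passing tests
therefore demonstrate correctness of the machinery under the stated
generative model, not agreement with the original dataset's numbers.

## Validation performed

The test suite and `scripts/acceptance.R` recompute, from scratch:

* exact agreement of all centralities with brute-force oracles on hundreds
  of random graphs, and of the tabular `A` with the kinship recursion on
  100 random pedigrees (`A A^{-1} = I` to 1e-8);
* recovery of h² = 0.30 / c² = 0.10 by the linear model (n = 2,000, 80
  sires, 78 pens; posterior mean within ±0.08, HPD95% coverage in ≥17 of
  20 replicates), of liability h² = 0.20 at prevalence 0.25 by the
  threshold model, and of rg = 0.9 (within ±0.15) by the bivariate model;
* agreement of the sampler with an independently coded conjugate Gibbs
  sampler on unrelated animals, and of posterior fixed effects and EBVs
  with the known-variance GLS/BLUP solution of the mixed-model equations;
* the directional selection-response sign pattern on paper-like data:
  animals in the lowest EBV decile for eigenvector centrality have a
  negative mean anterior-SL24h EBV, and the lowest decile for clustering a
  negative mean posterior-SL3wk EBV, in ≥8 of 10 seeds.

## Numerical choices and degenerate inputs

Tie rules are fixed and tested: HPD windows towards the smallest lower
bound, selection cuts by stable input order, quartile ties all "high",
maximum-clique ties flag every largest clique. Degenerate inputs (edgeless
pens, constant traits, all-zero binary responses, singleton pens under SD
ranking, duplicated traits in a bivariate fit) either return the documented
convention with a warning or fail with a specific error. The truncated
normal sampler uses CDF inversion with clamping at 1e-16, adequate for the
moderate prevalences of these traits. Chains are reproducible bit-for-bit
given `mcmc_settings(seed = )`, and every generator function is
deterministic given its seed.

## Known limitations

Single-site Gibbs mixes slowly for parameters that are weakly identified —
notably separating `s2_a` from `s2_e` without close relatives, and
threshold-model variances at extreme prevalence; the Raftery–Lewis
diagnostic should be consulted before shortening chains further. Bivariate
models assume both traits observed on the same records (rows missing either
trait are dropped). The threshold–threshold sampler is experimental. No
REML, no social genetic effects, no genomic relationship matrices, at most
two traits per model.
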