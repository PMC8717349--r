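---
title: "Methods: from assigned amplicon hits to diet comparison"
author: "mbdiet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from assigned amplicon hits to diet comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbdiet)
```

`mbdiet` implements the downstream half of a dietary DNA metabarcoding
study: everything after reads have been trimmed, denoised into ZOTUs and
assigned a best taxonomic hit. This vignette explains the models and
procedures, the parameters that matter and their defaults, the numerical
choices, what the synthetic-data generator does and does not emulate, and
the known limitations.

## Inclusion criteria and the incidence matrix

A marker-level assignment is trustworthy only in proportion to its
evidence. For the COI barcode, percent identity to the reference decides
the rank at which a hit may be reported: at or above 98 % the species name
is kept; in [96, 98) the hit is demoted to its family; in [90, 96) to its
order; below 90 % it is discarded. Bands are closed on the lower bound and
open on the upper, so 98.0 is a species-level hit and 96.0 a family-level
one. The 16S marker is more conserved, and its reference databases are
patchier, so instead of rank demotion a 16S hit is kept at its assigned
rank only when identity (≥ 90 %), alignment length (≥ 100 bp) and E-value
(< 10⁻⁷) all pass. A hit demoted to a rank its taxonomy does not resolve
is rejected (`"rank unavailable"`) rather than silently promoted.

The read-count screen (≥ 10 reads by default) applies to the *final
assigned taxon*: reads are first summed over ZOTUs that map to the same
taxon within a sample and marker, because several denoised variants of one
prey species are still one prey species. Sample-level QC removes samples
below 1000 total reads and samples that pass the depth check but retain no
prey detection; by default the depth criterion pools both markers'
totals (`mode = "per_marker"` requires each marker separately — the
stricter reading; the pooled default is the more permissive one and is
configurable because either is defensible).

Detections from the two markers are then merged into a binary samples ×
taxa incidence matrix, counting a taxon once per sample however many
markers detected it. A taxon's identity is its (rank, name) pair:
`family:Tortricidae` and `species:Ectropis obliqua` are distinct columns,
because a family-level detection asserts strictly less than a species-level
one. All downstream statistics operate on this matrix.

## Diet profiles and indices

The percentage of occurrence (POO) of taxon *i* in one predator's diet is
its incidence count divided by the predator's total prey occurrences, so
the profile sums to exactly 1 and every index below is a function of a
proper proportion vector.

* **Hill numbers** `^qD = (Σ p_i^q)^{1/(1−q)}`, with the continuous limit
  `exp(−Σ p_i ln p_i)` at q = 1, give the "effective number of equally
  common prey taxa" at rarity-sensitivity q; the package reports q = 0, 1,
  2 by default.
* **Shannon** uses the natural logarithm; **Simpson** is reported as
  `1 − D` with `D = Σ p_i²`.
* **Levins breadth** `B = 1/Σ p_i²` is normalised as `(B − 1)/(S − 1)`
  where S defaults to the predator's own observed consumed-taxon count.
  These identities are exploited in the tests: `^1D = exp(H')` and
  `^2D = 1/(1 − Simpson) = B` must agree to 10⁻⁹ on random profiles.
  When S = 1 the normalisation is 0/0; the package defines it as 0
  (a one-resource diet is maximally specialised, matching the index's
  "0 = highly specialised" reading).
* **Pianka overlap** `O_jk = Σ p_ij p_ik / √(Σ p_ij² Σ p_ik²)` is computed
  on profiles aligned over the union of taxa. When profiles are aggregated
  to a coarser rank, POO is summed within the higher taxon; an item
  resolved only to a coarser rank keeps its own identity — it is never
  split downward, which would fabricate resolution.

The **core diet** restricts a predator's matrix to taxa consumed more than
once; indices recomputed on it describe the repeatable part of the diet.
Per-rank overlap counts (the numbers behind a Venn diagram) roll taxa up
with the same never-finer rule, and the family-level partition table
re-includes a taxon consumed once by one predator when the other consumed
it more than once, so shared families are not hidden by the core cutoff.
Per-sample prey counts are compared across predators with the unpaired
Wilcoxon rank-sum test: the exact null distribution when both groups are
small (n₁ + n₂ ≤ 20) and tie-free, otherwise the tie-corrected normal
approximation with a 0.5 continuity correction. The exact mode agrees with
brute-force enumeration by construction; the normal approximation is an
approximation, and at very small group sizes its two-sided p can differ
from the exact value by far more than 0.01 (up to ≈ 0.09 at n₁ = n₂ = 2),
which is precisely why the exact mode is the small-sample default.

## Richness estimation

Sample-based accumulation curves use random permutations of sample order
(delegated to `vegan::specaccum`, 100 permutations by default, seeded).
Completeness is estimated with coverage-based nonparametric estimators
with the conventional rare-group cutoff k = 10:

* species level: the incidence-based **ICE** (Lee–Chao), built from
  `Q_j`, the number of taxa found in exactly j sampling units, with the
  Chao2 estimator (bias-corrected when `Q_2 = 0`) as the flagged fallback
  when every infrequent taxon is a singleton and the coverage estimate is
  zero;
* genus, family and order levels: incidence counts are summed within each
  higher taxon and treated as pseudo-abundances for the **ACE** estimator
  (Chao1 fallback). Feeding summed incidences into an abundance-based
  estimator is methodologically unusual — the "abundances" are bounded by
  the number of samples and are not independent — but it is the
  established workflow this package mirrors for comparability, and it is
  implemented exactly as described. Coverage is reported as
  `S_obs / S_est`.

A taxon lacking the requested ancestor rank is grouped under its finest
available ancestor and the event is messaged, so mixed-rank matrices
(a by-product of COI rank demotion) aggregate without silent loss.

## Capture-mode inference

Prey are classified by two traits, looked up at the taxon's own rank or
its nearest classified ancestor: non-volant prey, and volant but diurnal
prey (inactive, hence resting, at night), are *gleaning*-likely; volant
and nocturnal prey are *hawking*-likely; a volant taxon with unknown diel
activity, or a taxon absent from the trait table, is *undecided* and
excluded from modelling (but kept in the tally report). The classification
is a likelihood statement, not a certainty — nocturnal moths at rest can
be gleaned — and the model inherits that caveat.

Each sample contributes one binomial observation: `y_s` gleaning-likely
items out of `n_s` classified items. The model is

`y_s ~ Binomial(n_s, π_s)`, `logit π_s = β₀ + β₁·I[species] + u_s`,
`u_s ~ N(0, σ_u²)`,

with one random intercept per sample. With a single observation per
sample this is an observation-level random effect: its job is to absorb
extra-binomial variation (samples differ in habitat, night, individual
bat), and without it the binomial standard errors would be overconfident.
The reference level is `"Myotis ikonnikovi"` when present (so β₁ > 0 means
more gleaning in the other species); otherwise the first level
alphabetically, configurable via `reference`.

The marginal likelihood integrates each `u_s` out by **adaptive
Gauss–Hermite quadrature**: the integrand's conditional mode is found by
Newton iterations (the objective is strictly concave), the quadrature grid
is centred there and scaled by the conditional curvature, and `n_quad`
nodes (default 15; `n_quad = 1` is exactly the Laplace approximation)
evaluate the integral in log space with a max-shift for stability.
Identical (y, n, design) observations are collapsed with multiplicity
weights — an exact rewrite of the likelihood that matters because the
parametric bootstrap refits the model tens of thousands of times.
Optimisation is BFGS on (β, log σ_u) with a relative-tolerance stop at
1e-9; σ̂_u below 10⁻⁶ is reported as 0, where the likelihood continuously
equals the plain binomial GLM's (a property the tests assert against
`glm()`, and the full quadrature fit is cross-checked against
`lme4::glmer` at matching `nAGQ`). Standard errors come from the inverse
observed information of all parameters at the optimum; when σ̂_u sits on
the boundary the flat log-σ direction is dropped first.

The species effect is tested twice: a Wald χ² (= z² for this single
two-level factor, so Type II and the simple test coincide) and a
**parametric-bootstrap LRT** — B datasets simulated from the fitted null,
both models refitted on each, `p = (1 + #{LRT_b ≥ LRT}) / (B_eff + 1)`
with non-convergent replicates dropped and reported. B defaults to 500.
Marginal probabilities per species are the inverse-logit of the
fixed-effect linear predictor at u = 0, with delta-method standard errors
from the fixed-effect covariance — the stated convention; a
population-averaged probability (integrating over u) would be slightly
shrunk toward ½ and is not what is reported here.

## The synthetic-data generator

`synth_config()` describes a two-predator study; its defaults *are* the
study conditions the package is sized for: 53 and 45 samples, a 300-taxon
regional prey pool of which half is available to both predators, symmetric
Dirichlet(1) prey preferences over each predator's available taxa (which
yields a true Pianka overlap around 0.3), Poisson prey counts per sample
with means 6 and 14, per-item detection probabilities 0.8 (COI) and 0.7
(16S), log-normal read counts, an identity mixture putting 75/12/8/5 % of
COI assignments in the species/family/order/failing bands, 5 % failing
16S assignments, and gleanable-diet targets of 0.37 and 0.21. The
`frac_gleanable` targets are preference-*mass* targets: shared taxa get the
mean target as their label probability and each predator's exclusive taxa
absorb the remainder, so differing targets create a genuine between-species
capture-mode effect (with defaults, a fitted odds ratio near 2.2) rather
than being averaged away by the shared pool. Sampling within a sample is
without replacement, matching incidence semantics. The two markers detect
independently by default; a Gaussian-copula correlation knob exists.

Ground truth (preference vectors, true overlap, true gleanable mass,
consumed incidence) is recorded before noise, which enables the strongest
tests in the suite: with perfect detection and all assignments in the
species band, the pipeline must return the consumed matrix *exactly*, and
the POO-based overlap estimate must sit within 0.03 of the generating
overlap at 200 samples per predator.

What the generator does **not** emulate: sequence-level artefacts
(chimeras, index hopping, reference-database gaps), seasonal or
site-structured diet variation, correlated detection between related taxa,
and predator individuals sampled repeatedly. Passing tests therefore
demonstrate that the *analysis* is correct under the stated sampling
model, not that any particular field dataset meets that model.

## Numerical choices and simulation sizes

Tolerances and sizes used by the test suite are the package's own choices:
index identities are asserted to 10⁻⁹ over 1000 random profiles; ICE
recovery uses a 300-taxon pool sampled by 500 units (observed error ≈ 5 %,
asserted ≤ 10 %); GLMM parameter recovery uses 200 replicates of 50 + 50
samples (β₁ = ln 2, σ_u = 0.8) with Wald-interval coverage required in
[0.92, 0.98]; and the bootstrap LRT's type-I error is estimated from 200
null simulations of 25 + 25 samples with B = 59 bootstrap replicates each —
59 because 0.05 · (B + 1) is then an integer, making the exact-test
rejection probability exactly 0.05 under a continuous statistic. Seeds are
fixed throughout; the generator is byte-reproducible given its seed.

## Limitations

* POO weights every detection equally; read counts carry no abundance
  meaning here beyond the inclusion screen, so "diet proportion" means
  proportion of occurrences, not of biomass.
* Demoted (family/order-level) detections coexist with species-level ones;
  overlap and richness at fine ranks are therefore conservative for the
  demoted fraction of the data.
* The published Levins-breadth normalisation is sensitive to the choice of
  S; with the observed-taxon basis used here, values are not comparable
  across studies that used a different basis, and `s_basis` is exposed for
  that reason.
* The trait classification operates at family level or finer; order-level
  detections are usually `undecided` and drop out of the capture-mode
  model, shrinking its effective sample size.
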