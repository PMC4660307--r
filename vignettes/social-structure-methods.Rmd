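---
title: "Methods: association indices, permutation nulls and lagged association rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: association indices, permutation nulls and lagged association rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffsoc)
```

This vignette is the package's own account of the statistics it implements,
the assumptions behind them, and the design decisions taken where the
methodology left genuine choices open.

## Data model and the association definition

The unit of observation is one individual identified in one survey. Surveys
are grouped into *sampling periods* of one calendar day: treating the day as
the sampling period avoids replicating associations when the same
aggregation is photographed by two or three surveys on one day. Two
individuals are *associated* in a period when they occur together in at
least one group (survey) of that period. This is the "gambit of the group"
assumption: co-occurrence in a group is taken to reflect a social
relationship, which is reasonable for societies that travel in mixed
aggregations but blurs within-group social differentiation.

The inclusion filter retains individuals identified on strictly more than
`min_days` distinct days (default 6) *and* in at least `min_years` distinct
calendar years (default 4). We read the criterion as a pooled one — more
than six days overall, spread over at least four years — rather than
per-year; the per-year reading is available via `strict_per_year = TRUE`.
The pooled reading is the natural parse of a single combined criterion and
keeps the filter monotone in both arguments.

Sex classification from observation histories uses three rules: repeated
calf observations on different days across at least two seasons make a
female; a ten-year calf-free identification span makes a male; a nine-year
calf-free span qualifies when the animal was already independent and
distinctively notched at first identification. "Season" is not defined by
the sexing convention itself; we operationalise it as meteorological
quarters, the coarsest reading that still requires observations months
apart. The nine-year bound is justified by inter-birth intervals shorter
than eight years in this taxon: nine calf-free years of an adult female's
history would span at least one full inter-birth interval.

## Association indices

The half-weight index corrects for the chance that only one member of a
dyad is identified in a period; its tallies (`x`, `y_ab`, `y_a`, `y_b`) are
kept in full generality even though day-level association makes `y_ab`
(both identified, never together) rare. The HWIG rescales each dyad by the
product of the two individuals' total HWI sums. Two conventions needed
fixing:

* ΣHWI is the sum over individuals of their row sums, i.e. each unordered
  dyad counts twice. Under uniform pairwise association this makes every
  HWIG equal `N/(N-1)`, which tends to 1 from above as the society grows —
  matching the interpretation that HWIG ≈ 1 is "as expected given
  gregariousness". The alternative single-counting convention would put the
  uniform case at `N/(2(N-1))` ≈ 0.5, which contradicts that reading.
* Diagonals are excluded from all sums and means; individuals with zero
  row sums yield HWIG 0 and are flagged rather than producing 0/0.

Scaling every HWI by a constant leaves HWIG unchanged (the constant
cancels), which the tests assert numerically.

## The permutation null for nonrandom association

The null model permutes *groups within sampling periods* by checkerboard
swaps: two individuals in different groups of the same period are
exchanged. Each swap preserves every group's size and every individual's
number of sightings in every period, so the null conditions on both
gregariousness and observation effort, isolating companion *choice*. The
chain is sequential — each recorded permutation continues from the previous
state with a further `flips` swaps (defaults 10,000 × 100) — which is the
standard design for this test; successive null matrices are therefore
autocorrelated, and the p-value is a valid Monte-Carlo p for the chain's
stationary distribution. The test statistic is the coefficient of variation
(sample SD over mean) of all off-diagonal dyad values, zeros included; the
alternative is one-sided (higher observed CV = nonrandom preference). The
p-value uses the `(1 + b)/(1 + n)` estimator, so it can never be exactly
zero. Datasets in which no period contains two groups admit no swaps; the
result is flagged degenerate with p = 1 rather than silently passing.
A configurable `burn_in` is available but defaults to 0, the first set of
flips serving as the transient.

## Class-structured comparisons

Dyadic values sharing an individual are not independent, so both
comparison operations default to permuting *individual labels*, not dyad
values: the node-label (Mantel-type) test permutes class labels across
individuals and recomputes the within-minus-between statistic; the
randomization test for arbitrary dyad-set contrasts permutes the labels
that define the sets and rebuilds the sets each iteration. Permuting dyad
values directly remains available (`unit = "dyad"`) for set definitions
that are not label-expressible. P-values are two-sided by default; reports
carry the observed direction. For small societies the Monte-Carlo p
converges to the exact enumeration p over all label arrangements, which the
acceptance tests verify at N = 7.

## Social clustering

Average linkage operates on similarity directly: each step merges the pair
of clusters with the greatest mean pairwise index, recording that mean as
the merge height, so heights read as association levels. This is equivalent
in merge order to clustering on 1 − index but keeps the dendrogram axis in
index units. Ties are broken by the lexicographically smallest pair of
cluster labels (a cluster is labelled by its smallest member id), making
the tree fully deterministic and testable. Average linkage admits no
inversions, so heights are monotone non-increasing; `as.hclust()` exposes
the tree on the 1 − index distance scale for cutting and plotting, and
Newick export uses those distances as branch lengths. The cophenetic
correlation (Pearson, over all dyads, between index and merge height of the
lowest common cluster) is the fit diagnostic, with ≥ 0.8 flagged as a good
match; constant matrices make it undefined and are flagged, not forced.
The pipeline clusters both sexes but writes only the male trees as primary
artifacts, flagging any clustering whose cophenetic correlation is
inadequate.

## Standardized lagged association rate

For every ordered pair of periods `(t1, t2)` and pair of subset individuals
`(i, j)` associated at `t1`, with `i` identified at `t2`, the numerator
counts the cases where `i` and `j` are associated at `t2` and the
denominator counts `i`'s subset associates at `t2`. The ratio estimates the
probability that a randomly chosen associate of `i` after lag `td` is still
`j`. Directional (ordered-pair) counting is used, consistent with that
definition.

**Null rate.** Under exchangeable random association the identified counts
per period cancel exactly between numerator and denominator, leaving
`1/(N-1)` for a subset of N individuals: whatever the group sizes, a
randomly chosen associate is any of the other N − 1 individuals with equal
probability. This constant is what the estimator converges to on
random-association data, which the tests check via the jackknife.

**Display binning vs fitting.** Lags span days to years, so the displayed
curve uses logarithmically spaced bins (default 8 over the observed lag
range) with delete-one-block jackknife SEs, the blocks being 15 contiguous
date blocks — temporal blocks, not individuals, because the estimator's
unit of information is the period pair. Model *fitting*, however, uses
exact day-lag tallies (every distinct integer lag its own cell): over a
wide log bin the rate can change several-fold, and evaluating a model at a
single bin centre against pooled tallies would misattribute that
within-bin variation to model misfit. With daily lags the exact-lag
likelihood has no such bias and costs nothing extra.

**Likelihood, QAIC and ĉ.** The four temporal models are fitted by
maximising the binomial log-likelihood of the per-lag tallies. The tallies
are not truly binomial — the same dyad contributes to many period pairs —
so model comparison uses QAIC with ĉ estimated as the Pearson χ²/df of the
most general (four-parameter) model, floored at 1. Models with ΔQAIC ≤ 2
are flagged strongly supported. Parameters are transformed (logistic for
levels, log for rates, with the two-component models parameterised so the
component levels sum to at most 1), guaranteeing predicted rates in [0, 1]
at any lag. Optimisation runs a deterministic ladder of starts — a grid of
decay rates spanning the observed lag range plus the maxima of each nested
submodel — followed by a BFGS polish, so the maximised likelihoods respect
the model nesting up to optimizer tolerance and fits are exactly
reproducible. The constant model's MLE is closed-form (pooled rate).

## The synthetic society generator

The generator emulates the survey design of a seven-year coastal
photo-identification study: 84 observation days spread over 7 years, one to
three surveys per day (probabilities 0.70/0.24/0.06, giving ≈ 114 surveys),
and a community of 123 individuals in four sex-by-class cells
(54/14/51/4). Detection is per individual per survey, a baseline (0.55)
scaled by a lognormal gregariousness multiplier (σ = 0.25) — so sighting
frequency tracks gregariousness, as in real identification data. Detected
individuals are partitioned into groups by greedy agglomeration on an
affinity score: a baseline (1) plus structural boosts — within-class male
affinity (+3), an extra SC-male bond (+3, making the small southern unit
tight), male-to-female affinity by male class (+1.5 for NC, 0 for SC) —
plus fresh per-survey exponential noise (scale 1), merging while the
cluster-pair mean stays at or above a threshold (3, or 4 in the sparse
scenarios) under a size cap (100). Females carry no structural affinity:
their grouping is noise-driven and therefore fluid. These values were
chosen once to reproduce the qualitative regime of the emulated system — a
large northern aggregation of roughly eighty animals, a small cohesive
southern male unit, strong male class assortativity, no female class
structure — and are exposed as `ff_config()` parameters rather than
constants.

Temporal scenarios use explicit dyadic bonds instead of affinity grouping:
individuals are paired, bonds dissolve with a per-day hazard `b`
(exponential lifetimes, mean 1/b), and members re-pair. In the
casual-acquaintances scenario dissolved partners never re-pair — the
defining property of casual acquaintance, association for a time and then
never again — so the generating SLAR is a clean `a·exp(-b·td)` with no
random-re-encounter floor; with the hazard at zero, bonds are permanent
preferred companionships. Calf histories are generated for a configurable
fraction of females with inter-birth intervals drawn from [3, 8) years,
so the sex-classification rules can be exercised against ground truth.

What the generator does *not* emulate: spatial structure and ranging,
demography (births and deaths beyond calf records), effort variation
between surveys, misidentification, and any dominance or kinship structure.
Tests passing on this generator therefore demonstrate correctness of the
estimators and the qualitative behaviour of the pipeline under the stated
social structure — not robustness to the full messiness of field data.

## Problem sizes used in the tests

The test suite runs the oracle equivalences at exhaustive-enumeration sizes
(N ≤ 8 individuals, ≤ 20 periods for the index oracle; N ≤ 7 for exact
permutation enumeration; N ≤ 6 for clustering; N ≤ 5 for the SLAR
quadruple-loop) and the calibration and recovery studies at the study-shaped
sizes: 200 replicates of the 30-individual random-association scenario for
type-I error, 50 replicates each of the 40-individual/500-period bond
scenarios for model recovery, and 50 replicates of the full 123-individual
society for the end-to-end structure checks. These sizes give binomial
standard errors comfortably inside the asserted bands while keeping the
default suite in the minutes range.

## Known limitations

* The sequential permutation chain mixes slowly on datasets with few
  multi-group periods; the degenerate flag catches the extreme case but
  near-degenerate data deserve a larger `flips` setting.
* ĉ from the most general model's Pearson dispersion is a coarse
  correction for the dependence among period-pair tallies; QAIC
  differences near the ΔQAIC ≤ 2 threshold should be read qualitatively.
* The long-lag tail of a SLAR realisation is dominated by the few bonds
  that happen to survive longest, so single-run tail rates are noisy even
  when the population curve is exactly exponential; the jackknife SEs
  reflect this.
* `reproductive_condition` classifies from the most recent record in a
  dependency window (default 3 years) and does not age a calf record into
  a juvenile record; the window is configurable.
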