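# ffsoc — fission–fusion social structure from photo-identification records

`ffsoc` is an R package for analysing the social structure of fission–fusion
animal societies — coastal dolphin communities are the motivating case — from
long-term photo-identification sighting records. It is aimed at behavioural
ecologists who have a table of *who was seen in which survey on which day*
plus individual attributes (sex, community class), and who want the standard
association-analysis workflow: dyadic association indices, permutation tests
for nonrandom association, class-structured comparisons, social dendrograms,
and temporal models of association decay. A seeded synthetic-society
generator reproduces the statistical structure of such data, so the entire
pipeline is testable without field data.

## The statistics at the core

**Half-weight association index.** For a dyad *(a, b)*, with sampling
periods (calendar days) as the unit,

    HWI_ab = x / (x + y_ab + 0.5 * (y_a + y_b))

where *x* is the number of periods the two were associated (sighted in the
same group), *y_ab* the periods both were identified but never together,
and *y_a*, *y_b* the periods only one was identified. HWI is 0 for dyads
never together and 1 for dyads always together.

**Gregariousness correction (HWIG).**

    HWIG_ab = HWI_ab * ΣHWI / (ΣHWI_a * ΣHWI_b)

with ΣHWI_a the sum of *a*'s HWI values over all partners and ΣHWI the sum
of those row sums. HWIG > 1 means the dyad associates more than expected
given the two individuals' gregariousness.

**Permutation test for nonrandom association.** Groups are permuted within
sampling periods by checkerboard swaps ("flips") that preserve every group's
size and every individual's sighting record; a sequential chain (default
10,000 permutations × 100 flips) yields a null distribution for the
coefficient of variation of the dyadic indices. A significantly higher
observed CV indicates preferred/avoided companionships.

**Class-structured tests.** A node-label permutation test compares mean
within-class vs between-class indices (rows and columns permuted together,
respecting dyadic non-independence), and randomization tests compare means
of arbitrary dyad sets (e.g. NC-male–female vs SC-male–female blocks).

**Social clustering.** Average-linkage agglomerative clustering directly on
similarity, with deterministic tie-breaking, cophenetic correlation as the
fit diagnostic (≥ 0.8 read as a faithful dendrogram) and Newick export.

**Standardized lagged association rate (SLAR).** The probability that, given
two individuals associated at some time, a randomly chosen associate of the
first after a lag *td* (days) is that same individual. Four temporal models
are fitted by binomial maximum likelihood —

| model | g'(td) |
| --- | --- |
| preferred companions | a |
| casual acquaintances | a·exp(−b·td) |
| constant companions + casual acquaintances | a + c·exp(−d·td) |
| two levels of casual acquaintances | a·exp(−b·td) + c·exp(−d·td) |

— and compared by QAIC = −2 logL/ĉ + 2k with the overdispersion ĉ taken
from the Pearson dispersion of the most general model; ΔQAIC ≤ 2 flags
strongly supported models. Jackknifing over contiguous date blocks gives
per-bin standard errors, and the null rate under random association is
1/(N−1) for a subset of N individuals.

## Worked example

```r
library(ffsoc)

soc <- generate_scenario("paper_like", seed = 1)     # 123-individual society
d   <- filter_individuals(soc$dataset)               # > 6 days over >= 4 years
d
#> sighting_data: 123 individuals, 84 sampling periods, 1096 groups
#>   date span: 1994-01-15 to 2000-12-20

hwi  <- half_weight_matrix(d)
hwi
#> assoc_matrix (HWI): 123 individuals, 7503 dyads
#>   mean 0.2877  sd 0.2080  max 0.9571  prop. zero 0.177
hwig <- hwig_matrix(hwi)

cv_test(d, "HWI", n_permutations = 1000, flips = 100, seed = 2)
#> Permutation test for nonrandom association (HWI)
#>   observed CV: 0.7229   null CV mean: 0.2842
#>   one-sided P = 0.000999  (1000 permutations x 100 flips)

ind   <- d$individuals
males <- ind$id[ind$sex == "male"]
cls   <- setNames(ind$community_class, ind$id)
mantel_class_test(hwig, cls[males], n_permutations = 1000, seed = 3)
#> Node-label permutation test (within vs between class)
#>   within mean 3.2283  between mean 0.0145  statistic 3.2138
#>   P = 0.000999 (two.sided, 1000 permutations)

sc  <- males[cls[males] == "SC"]
fit_slar_models(d, subset = sc)
#> SLAR temporal models (binomial likelihood, QAIC selection)
#>   overdispersion c_hat = 1; best model: casual_acquaintances
#>   ...                                     qaic      delta_qaic  supported
#>   Preferred companions                    950502.2  0.2271      TRUE
#>   Casual acquaintances                    950502.0  0.0000      TRUE
#>   Constant companions and casual acq.     950504.0  2.0000      FALSE
#>   Two levels of casual acquaintances      950506.0  4.0000      FALSE
```

The observed CV far above its permutation null says companionships are
nonrandom; the male class test says males associate overwhelmingly within
their community class (within-class mean HWIG 3.23 vs 0.01 between); and the
SC-male SLAR sits at its null level 1/(14−1) ≈ 0.077 with the constant and
decaying models statistically tied — stable companionships with no
detectable turnover over the study span.

The whole analysis (filter → indices → permutation tests → class
comparisons → clustering → SLAR → reproductive-condition table) runs as one
pipeline, from R (`run_pipeline(analysis_config(...))`) or from the shell
via the bundled CLI:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "ffsoc.R", package = "ffsoc"))') \
    run-all --scenario paper_like --seed 1 --out-dir results/ --fast
```

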