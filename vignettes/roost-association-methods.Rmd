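---
title: "Inferring social structure from roost captures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring social structure from roost captures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`roostnet` infers social structure in fission-fusion, group-roosting animals
(its motivating system is a neotropical bat with two genetically distinct
populations, female philopatry and male dispersal) from opportunistic roost
captures of individually marked animals. This vignette explains the models and
conventions the package implements, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the numerical choices
made where the design was genuinely open.

```{r setup, message = FALSE}
library(roostnet)
```

## Data model

A **capture record** is one individual in one netting of one day roost:
`bat_id, date, roost_id, population, sex, age_class, repro_status`. A
**capture event** ("group capture") is the set of records sharing
`(date, roost_id)`: each netting of a roost on a date is one observation
occasion, and two captures of the same roost on different dates are distinct
events. The event key assumes a roost is not netted twice on one date; the
readers reject a bat duplicated within an event, unresolved roost ids, and
unknown sex/age codes, naming the offending rows.

Roost registries declare their coordinate system in a header line: planar
coordinates in metres (Euclidean distances) or geographic lon/lat
(great-circle distances). Dyadic relatedness is consumed as a symmetric
matrix in [0, 1] — typically a marker-based maximum-likelihood estimate
produced outside this package — with empty cells for ungenotyped dyads.

Filtering applies the population and adults-only restrictions first and then
the minimum-sightings rule on the restricted record set, so
`min_sightings = 4` means "captured at least four times as an adult".
Association estimates from one or two sightings are noise; the
sightings-threshold curve (`sightings_threshold_curve()`, `plot_sightings_curve()`)
shows the precision/sample-size trade-off that motivates the threshold.

## Association and social differentiation

Two bats are associated when they occupy the same day roost at the same time.
The dyadic index is the **simple ratio index** (SRI),

$$\mathrm{SRI}_{ab} = \frac{x}{x + y_{ab} + y_a + y_b},$$

with counts taken over *sampling periods*: $x$ periods with $a$ and $b$ in
the same group, $y_{ab}$ periods with both observed but never together,
$y_a, y_b$ periods with only one observed. The SRI estimates the probability
the pair is together given at least one is seen. More elaborate indices
(half-weight and relatives) require assumptions about missed observations
that opportunistic roost captures cannot support, so they are deliberately
not provided.

**Sampling period.** The default period is the `(date, population)`
combination: two bats captured the same day in different roosts of one
population were demonstrably apart, while bats in different populations are
never co-sampled (their denominators reduce to $y_a + y_b$, so their SRI sits
near zero and cross-population dyads are excluded from within-population
analyses by masking). The published convention of the motivating study does
not pin this down, so `period = "event"` (each capture event its own period)
is available as an alternative; the two agree unless a bat set is observed
more than once per date.

**Social differentiation** is the coefficient of variation of the SRI over
defined, masked, off-diagonal dyads (each unordered dyad once): sd/mean, with
the *population* standard deviation (divide by the number of dyads) as the
default convention and the sample convention switchable. A dyad with a
positive denominator and no joint sightings is a true zero and is retained;
only dyads with denominator zero are undefined and dropped.

## Datastream permutation null

Bats can appear associated merely because they prefer the same roost or were
present in the same years. The null model therefore permutes the *datastream*
rather than the network: single observations (one bat in one event) are
repeatedly swapped between events **within the same population, roost and
year**, which preserves every event's size, every bat's total sighting count,
and every bat's per-(population, roost, year) visit counts. A proposal is
rejected when the two observations share an event or a bat, or when a swap
would duplicate a bat within an event; the proposal kernel is symmetric, so
the chain's stationary distribution is uniform over the reachable
configurations (the test suite verifies this by exhaustive enumeration on a
toy stratum).

Defaults: 5000 sampled networks, 100 accepted swaps between samples, 1000
accepted burn-in swaps. The published analysis states only the network count;
burn-in and thinning follow common datastream-permutation practice, are
config-exposed, and are echoed in every report. The accepted-swap clock (not
the proposal clock) drives thinning so that rejection-heavy strata do not
stall mixing. The chain is implemented in C++ with R's RNG, so a seed makes
the whole network stream bit-identical.

**Empirical p-values** are one-sided tail proportions with ties counted as
extreme; two-sided values double the smaller tail (capped at 1). A zero tail
count is reported as the bound `< 1/n` — with 5000 networks, `< 0.0002` —
rather than as an exact zero.

## Matrix tests of kin-biased association

`mantel_test()` correlates the vectorized defined lower triangles of two
dyadic matrices and assesses it against joint row/column permutations of the
second matrix (node permutation), with the doubled two-sided convention.
`dyad_type_matrix()` builds the binary female-female / male-male /
female-male indicators, which partition all dyads of sexed individuals.

`qap_regression()` fits ordinary least squares over the defined dyads
(intercept included, raw scale by default so coefficients are interpretable
as association-per-unit-relatedness; a standardize flag exists for
comparability) and compares each coefficient against one of two nulls:

* **node permutation** — refit after jointly permuting the response's rows
  and columns; or
* **custom (pre-network) nulls** — refit with each datastream-permuted
  association matrix as the response against the *unpermuted* predictors,
  which is the appropriate null when shared roosts and years must be
  controlled.

Estimation is plain OLS plus a permutation reference distribution, without
semi-partialling: the headline analyses test one predictor at a time against
custom nulls, and a multi-predictor call is supported but documented as a
joint refit. Collinear or constant predictors are rejected by name. Sex-subset
analyses subset the bats (and the same null networks) before vectorizing;
the SRI values themselves depend only on each dyad's own observations, so no
recomputation is needed. Undefined dyads are dropped listwise.

`kin_bias_suite()` bundles the canonical battery: Mantel tests of each
dyad-type indicator against relatedness over the genotyped adults (this set
is usually wider than the well-sampled association subset, so an explicit
bat list is accepted); QAP of association on each same-sex indicator; and QAP
of association on relatedness within all adults, females only, and males
only — all QAPs against one stream of datastream nulls, with statistics
computed per emission so memory stays flat at any network count.

## Univariate permutation tests

All univariate inference is permutation-based; no parametric t or F tests
are used.

* `permuted_mean_diff_test()` — statistic `mean(group1) − mean(group2)` in
  factor-level order, labels shuffled (default 10000 times), doubled
  two-sided p. `exact = TRUE` enumerates every split, which the tests use to
  check Monte-Carlo agreement with an exhaustive oracle.
* `permuted_variance_ratio_test()` — statistic `var(group1)/var(group2)`
  (default 5000 shuffles). The report states the orientation; with groups
  ordered males/females, female philopatry shows up as F well below 1. A
  zero-variance denominator yields an infinite statistic whose permutation p
  remains defined.
* `juvenile_recapture_spans()` — days between first juvenile capture and last
  adult capture, for bats seen in both age classes; greater female span
  variance is the capture-record signature of female philopatry.
* `two_male_relatedness_null()` — for events holding exactly two reproductive
  (scrotal) males, compares their mean relatedness with resampled pairs of
  adult males from the same population and calendar year ("the same times and
  locations"; a roost-level pool is switchable). The 95% CI is the 2.5/97.5
  percentile of the replicate means. The pool definition is an
  interpretation: the source analysis does not define it, and population-year
  is the widest pool consistent with "same times and locations".

## The colony simulator

`simulate_colony()` generates everything the pipeline consumes — capture
records, roost registry, relatedness matrix — from a known ground truth, so
every stage is testable and the whole pipeline can be calibrated without any
field data. It emulates:

* **two closed populations** whose bats never mix;
* **overlapping generations** (founders plus one potential pup per
  female-year, `pup_rate` default 0.5);
* **female philopatry and near-complete male dispersal**: individuals are
  juveniles in their birth year, adults from the next, and males leave the
  study area with probability 0.95 on reaching sexual maturity at the end of
  their first adult year. Dispersal at the *end of the first adult year* (not
  at age 1) is deliberate: it lets dispersing males be recaptured as young
  adults but never as older ones, which is exactly the recapture signature
  the philopatry test detects;
* **fission-fusion roosting**: each day every population's adults assort into
  `groups_per_day` groups; a group relocates wholesale to an empty roost with
  probability 0.25 per day;
* **kin-biased and partner-preferring group choice**: a bat joins the group
  maximising `pi * mean(past association with members) + kappa *
  mean(relatedness to members)` (the kin term for females only) plus
  N(0, `choice_noise_sd`) noise. With `kappa = pi = 0` every bat's choice is
  exactly uniform — the calibration null. When preferences are on, a soft
  capacity of 1.5x the balanced group size stops the trivial fixed point in
  which the whole population accretes into one group; under the null the cap
  is bypassed, so the null stays exactly uniform;
* **imperfect capture**: on each of `captures_per_year` occasions one
  occupied roost is netted and each bat present is recorded independently
  with `detection_prob` 0.85 (escapes are misses);
* **relatedness estimation noise**: the emitted matrix is the pedigree
  relatedness (2x kinship from the standard recursive algorithm) plus
  truncated Gaussian noise (sd 0.05), emulating marker-based estimation
  error; the noise-free matrix is also returned.

Default scale matches the motivating study's order of magnitude: 60 founders,
6 years, 16 roosts per population, 8 groups per population-day, 18 group
captures per year (~110 events), weekly roosting snapshots (52 simulated
days per year — captures sample these, so finer temporal resolution would add
cost without adding observable structure).

What the generator does **not** emulate: seasonal reproduction and capture
effort, mortality (a six-year window over a long-lived species), immigration,
roost microclimate preferences, within-day roost switching, and any
relationship between reproductive status and grouping beyond random
assignment at capture. Calibration and power results therefore show that the
statistics behave correctly under this generative model, not that any field
dataset satisfies its assumptions.

## Calibration and parameter recovery

Two simulation studies back the inference machinery (both run in the test
suite; sizes chosen to keep hundreds of replicates affordable):

* **Calibration.** 500 no-preference datasets (`kappa = pi = 0`; reduced
  scale: 16 founders, 3 years, 6 roosts and 3 groups per population, 26
  days and 15 captures per year), 200 null networks each. The
  social-differentiation CV test and the female-subset QAP relatedness test
  each reject at a rate statistically indistinguishable from the nominal
  alpha = 0.05 (binomial 99% band; a 300-replicate pilot gave 0.057 and
  0.047).
* **Parameter recovery.** At the documented operating point `kappa = 14`
  (females only), `pi = 2`, study-scale defaults otherwise, at least 80% of
  100 replicates yield a significantly positive female-subset QAP
  relatedness coefficient together with a non-significant male-subset
  coefficient — the qualitative pattern the method is meant to detect,
  recovered from known ground truth. The operating point was chosen by a
  pilot power analysis (kappa 10 gives roughly 83% joint success, 14 gives
  well above 90%) and then frozen.

## Numerical choices and degenerate inputs

* Ties in empirical p-values count as extreme (conservative); zero tail
  counts are reported as bounds.
* The CV uses the population-sd convention by default; both conventions are
  exposed because usage in the literature varies.
* OLS is solved by QR; rank deficiency is reported as a collinearity error
  naming the offending predictor matrices rather than silently dropping
  terms.
* Swap proposals on degenerate strata (single event or single bat) are
  rejected, never forced; a dataset in which *no* stratum spans two events
  fails fast with advice that datastream permutation is impossible.
* Single-roost bats contribute a mean roost distance of 0 (not missing), so
  the sex comparison keeps its full sample; missing coordinates flag the
  distance as `NA`.
* Empty filter results warn and return empty datasets rather than erroring,
  so pipelines can report attrition.
* Group-choice ties (identical scores) are broken by the Gaussian noise term;
  with noise sd 0 the `which.max` tie-break is deterministic by group index.

## Known limitations

* The `(date, roost)` event key cannot represent two nettings of one roost on
  one day.
* Node-permutation Mantel/QAP p-values are approximate under strong
  row/column heteroscedasticity; the headline tests use datastream nulls
  instead.
* The simulator's group-capacity rule is a modelling convenience; real roost
  capacities are unknown.
* Relatedness is consumed as given: genotyping error beyond symmetric noise,
  and uncertainty differences between dyads, are not modelled.
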