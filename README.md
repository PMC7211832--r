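# roostnet

Social-structure inference from roost-capture records of individually marked,
group-roosting animals. The package was built for the kind of dataset produced
by years of opportunistic roost netting in a fission–fusion bat population:
one row per bat per group capture, a registry of roost locations in two
genetically distinct populations, and a marker-based dyadic relatedness
matrix. From these it answers three questions: do individuals have preferred
roosting partners beyond what shared roosts and years explain; are
associations kin-biased, and in which sex; and do the capture records carry
the signature of female philopatry and male dispersal?

## The statistics at its core

* **Simple ratio index (SRI).** For a dyad, over sampling periods,
  `SRI = x / (x + y_ab + y_a + y_b)` — joint observations over occasions
  where at least one of the pair was seen: the probability the two are
  together given one was seen. The default sampling period is the
  (date, population) combination.
* **Social differentiation.** The coefficient of variation (sd/mean,
  population-sd convention) of the SRI across dyads: 0 when every dyad
  associates at the same rate, large when a few strong partnerships sit on a
  background of avoidance.
* **Datastream (pre-network) permutation null.** Null association networks
  are built by repeatedly swapping single bat observations between capture
  events *within the same population, roost and year*, preserving group
  sizes, per-bat sighting counts and per-bat roost/year/population visit
  counts — so location and time confounds survive into the null. Empirical
  p-values are doubled one-sided tail proportions; a zero tail count with
  5000 networks is reported as `p < 0.0002`.
* **Mantel and QAP matrix tests.** Kin bias is tested by correlating
  dyad-type indicator matrices with relatedness (Mantel, node permutation)
  and by OLS regression of the association matrix on relatedness or dyad-type
  over defined dyads (QAP), with coefficients referred either to node
  permutations or to the datastream nulls.
* **Permutation t/F analogues.** Sex differences in roost use and the
  variance of juvenile-to-adult recapture spans (philopatry) are tested by
  label-shuffling; exhaustive enumeration is available for small groups.
* **Colony simulator.** A pedigree-based generator (two closed populations,
  female philopatry, near-complete male dispersal at sexual maturity,
  fission–fusion roost switching, kin-biased female group choice, imperfect
  detection) produces capture datasets with known ground truth for
  calibration and power analysis.

## Worked example

Simulate a six-year study with kin-biased female roosting (`kin_bias = 14`),
partner preferences in both sexes (`partner_preference = 2`), then run the
headline analyses:

```r
library(roostnet)

sim <- simulate_colony(sim_config(kin_bias = 14, partner_preference = 2, seed = 7))
sim$dataset
#> <capture_dataset> 744 records | 210 bats | 108 events | 30 roosts | 2 populations
#>   dates 2013-01-01 to 2018-12-10 | group sizes 1-18 (median 6.5)

ds <- filter_captures(sim$dataset, adults_only = TRUE, min_sightings = 4)
gbi <- build_gbi(ds)
assoc <- simple_ratio_index(gbi)
assoc
#> <assoc_matrix> 68 bats | 2278 defined dyads | mean SRI 0.031 | period: date-population

# preferred associations: observed CV vs 1000 datastream null networks
cv <- social_differentiation(assoc)           # 2.06
nulls <- generate_null_networks(gbi, perm_config(n_networks = 1000, seed = 1))
empirical_p(cv, vapply(nulls, social_differentiation, numeric(1)))
#> empirical p (two-sided-doubled, 1000 nulls): 0.044

# kin-biased association among females, against the same nulls
fem <- gbi$bats$bat_id[gbi$bats$sex == "female"]
ids <- rownames(assoc$sri)
qap_regression(assoc, list(relatedness = sim$relatedness[ids, ids]),
               null = "custom", null_networks = nulls, bats = fem)
#> QAP regression (custom nulls, 1000): n = 40 bats, 780 dyads
#>         term       beta p_value p_display
#>  (Intercept) 0.02229796   0.252     0.252
#>  relatedness 0.42429031   0.000   < 0.001

# philopatry: variance of juvenile-to-adult recapture spans, males/females
spans <- juvenile_recapture_spans(sim$dataset)
permuted_variance_ratio_test(spans$span_days,
                             factor(spans$sex, c("male", "female")),
                             n_perm = 5000, seed = 1)
#> Permutation test: variance_ratio (male - female) = 0.3883, p 0.0236 [5000 permutations]
```

Reading: bats associate non-randomly even after conditioning on roost, year
and population (CV above the null band, p = 0.044); among females, each unit
of relatedness adds about 0.42 to the expected SRI (p below 1/1000 null
networks); and male recapture spans vary far less than female ones (F ≪ 1) —
males leave, females stay. `run_analysis()` wires all of these (plus group
composition, roost-use comparisons and the two-male within-group relatedness
null) into one tidy report; `tidy()`, `glance()` and `autoplot()` methods
cover the result objects, and `write_report()` / `write_simulation()` emit
CSV/markdown/JSON bundles. `inst/scripts/analyze.R` and
`inst/scripts/simulate.R` are thin command-line wrappers over yaml configs.

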