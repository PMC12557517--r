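# prrlife

Demographic analysis of **post-reproductive lifespan** in long-lived animal
populations, built for the kind of data long-term field studies actually
produce: longitudinal records of individually known females with estimated
birth dates (and per-female age errors of up to several years), staggered
study entry (left truncation via habituation or immigration) and exit before
death (right censoring via disappearance, emigration or study end). The
motivating system is wild mountain gorillas, but nothing in the package is
species-specific.

## What it computes

**Population level — post-reproductive representation (PrR).** From annual
age classes the package builds the fecundity schedule *m(x)* (parity events
per females observed at age *x*), the delayed-entry nonparametric
survivorship *l(x)* (product-limit by default, Breslow as an option, via the
`survival` package), and person-years lived after age *x*,
*T(x) = ∫ₓ l(y) dy*. Then

> PrR = T(M) / T(B),

where *B* and *M* are the ages by which 5% and 95% of cumulative population
fecundity have occurred: the share of adult female person-years lived after
reproductive cessation. Significance is assessed by shuffling the *m(x)*
values across age classes (survivorship held fixed, 10,000 iterations,
add-one p-value), and robustness to age-estimation error by re-running the
whole calculation with per-female uniform birth-date offsets (1,000
iterations).

**Individual level.** A female is classified post-reproductive when her
years between last birth and study exit exceed the mean + 2 SD of
*successful* interbirth intervals (intervals whose earlier infant survived
until the next birth).

**Validation.** An individual-based life-history simulator
(`sim_config()` / `generate_cohort()`) generates cohorts with the same
statistical structure — Gompertz mortality, truncated-normal intervals,
infant-death shortened intervals, optional reproductive cessation, staggered
observation, age errors — and `true_prr()` yields the generator's ground
truth from complete, uncensored lives, so the whole pipeline is testable
end-to-end without any field data.

## Worked example

```r
library(prrlife)

cfg <- sim_config(n_females = 25, seed = 1)   # reference study conditions
co  <- generate_cohort(cfg)
co
#> cohort: 25 females, 50 birth events
#>   observation: 1995-01-01 to 2025-01-01
#>   exit fates: alive=10 died=14 disappeared=1

rep <- run_full_analysis(co, n_permutations = 10000, n_uncertainty = 1000,
                         uncertainty_permutations = 1000, seed = 1)
#> 7 female(s) without recorded births excluded from classification
rep
#> post-reproductive lifespan analysis
#>   cohort: 25 females, 50 birth events
#>   PrR = 0.186 (B = 9.7 y, M = 28.9 y), permutation p = 0.0025
#>   age-uncertainty: PrR 0.175 +/- 0.021 over 1000 iterations
#>   successful IBIs: mean 5.10 y, SD 1.38 y -> threshold 7.85 y
#>   post-reproductive females: 4 of 18 classified
```

Reading the numbers: 5% of this cohort's cumulative fecundity falls before
age 9.7 and 95% before age 28.9; 18.6% of the person-years lived past 9.7
are lived past 28.9, and only 25 of 10,000 random fecundity shuffles did as
well or better (p = 0.0025). The estimate barely moves under birth-date
uncertainty (0.175 ± 0.021). Successful interbirth intervals average 5.10 y
(SD 1.38), so a female must outlive her last birth by more than 7.85 y to be
flagged; 4 of the 18 mothers qualify. Individual functions
(`exposure_schedule()`, `survivorship()`, `compute_prr()`,
`permutation_test()`, `uncertainty_simulation()`, `successful_ibis()`,
`prl_threshold()`, `classify_females()`) expose every intermediate, and
`write_report()` dumps all tables plus a JSON summary. Real data enter via
`read_cohort("females.csv", "births.csv")`; see `?cohort` for the column
contract.

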