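---
title: "Measuring post-reproductive lifespan from staggered-entry life histories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring post-reproductive lifespan from staggered-entry life histories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Long-term field studies of long-lived mammals record, for each identified
female, an estimated birth date (often with several years of uncertainty), the
dates she entered and left observation, how she left (death, disappearance,
emigration, or still present at study end), and the dates of her births.
Two features make these data statistically awkward:

* **Left truncation (delayed entry).** Females present when a group is
  habituated, or who immigrate later, are only observed from some adult age
  onward. Their survival before entry is unobserved, and conditioning on
  having survived to entry must be respected or old ages are over-represented.
* **Right censoring.** Most females are still alive at study end, or
  disappear or emigrate; only a minority have observed deaths.

`prrlife` asks of such data: do females live substantially beyond their
reproductive years, and is that pattern stronger than chance?

## The population-level statistic

Everything is computed on the age axis in decimal years (365.25-day years),
in one-year, left-closed age classes $[x, x+1)$.

1. **Fecundity** $m(x)$: parity events (twins count once) whose mother-age
   falls in class $x$, divided by the number of females observed in that
   class. The headcount denominator is the default; person-years of exposure
   is available via `denominator = "female_years"` and is the statistically
   preferable choice (see *Numerical choices*).
2. **Survivorship** $l(x)$: nonparametric delayed-entry estimator on the age
   axis. Each female is at risk on $(\text{entry age}, \text{exit age}]$ and
   contributes a death event only if her exit fate is `died`; `alive`,
   `disappeared` and `emigrated` censor. The default is the product-limit
   (Kaplan–Meier) form $\prod_{t_i \le x} (1 - d_i/n_i)$; `method = "breslow"`
   gives $\exp(-\hat H(x))$ with the Nelson–Aalen cumulative hazard, which is
   the baseline survival a covariate-free Cox model with Breslow ties would
   report. Both are computed by the `survival` package on counting-process
   data. The curve is anchored at $l = 1$ at the youngest entry age, the
   earliest age at which survival is identifiable; every ratio of
   person-years, and hence PrR, is invariant to that anchoring (this is
   tested).
3. **Person-years after $x$**: $T(x) = \int_x^{\omega} l(y)\,dy$, by the
   trapezoidal rule on the curve's grid with linear interpolation at $x$.
4. **Post-reproductive representation**:
   $$\mathrm{PrR} = \frac{T(M)}{T(B)},$$
   where $B$ and $M$ are the ages by which 5% and 95% of cumulative
   population fecundity have occurred. PrR is the fraction of adult female
   person-years lived after reproduction has (effectively) ceased: 0 when no
   female outlives the reproductive ages, 1 when reproduction is concentrated
   at a single age that everyone outlives.

Cumulative fecundity can be accumulated over $l(x)\,m(x)$ (realized cohort
fecundity, the default, with $l$ evaluated at class midpoints) or over $m(x)$
alone (`weighting = "m_only"`). The two readings of "population fecundity"
are both legitimate; they are one flag apart and both are exercised in the
tests.

**Significance.** The null hypothesis is that fecundity has no age pattern
beyond chance. Each of (by default) 10,000 iterations shuffles the $m(x)$
values across the age classes where $m$ is defined, holds $l$ fixed, and
recomputes PrR; the p-value is $(1 + \#\{\text{null} \ge
\text{observed}\})/(1 + n)$, the add-one estimator, which can never report
exactly zero. Survivorship is not recomputed because it is not a function of
the fecundity schedule.

**Age uncertainty.** Estimated birth dates carry a per-female half-width
error (zero for females born during the study). Each of (by default) 1,000
iterations draws one offset per female, uniform on $[-\text{error},
+\text{error}]$, and shifts her entry age, exit age and all her birth-event
ages together — the uncertainty is in her birth *date*, so all her ages share
one offset (`shift = "entry_exit"` restricts the shift to the observation
window for comparison). Schedules and survivorship are rebuilt per iteration
and the distribution of PrR and its p-value is returned.

## The individual-level criterion

A female is classified post-reproductive when her years between last recorded
birth and study exit strictly exceed the **mean + 2 SD of successful
interbirth intervals** (sample SD, $n-1$). An interval is *successful* only
if the earlier infant survived until the next birth (default rule; a
fixed-years survival cutoff is the alternative): infants that die soon after
birth are followed by abnormally short intervals, which would otherwise
deflate the threshold. Years since last birth run to study exit whatever the
exit fate, so living females can qualify. Females with no recorded birth are
excluded from interval statistics and classification (the quantity is
undefined for them) but still contribute exposure and survivorship.

## The synthetic-data generator

`sim_config()` / `generate_cohort()` produce cohorts with the structure the
analysis assumes, so the whole pipeline is testable without any field data.
Each female receives a Gompertz lifespan (default hazard $0.012\,
e^{0.06\,\mathrm{age}}$, truncated at 50 y), an age at first birth
$\sim N(10, 1.5^2)$ y (min 8), successful interbirth intervals $\sim N(5.1,
1.3^2)$ y, a 20% chance per birth that the infant dies quickly (followed by a
shorter $N(2, 0.6^2)$ y interval), an optional reproductive-cessation age
$\sim N(32, 2.5^2)$ y, and an observation window (default 1995–2025)
intersected with her life to yield habituation/immigration entry, exit fates,
left truncation and right censoring; habituated and immigrant females get an
age error uniform on [0, 4] y. All draws flow from one seed in a documented
order.

Defaults were fixed once from the study system's published biology: lifespans
rarely reaching 50, a maximum observed reproduction near 35 (hence a
cessation *mean* of 32 with SD 2.5 — the maximum of ~20 draws then lands near
35), interval moments 5.1/1.3, and birth-date errors up to several years.
Mortality and dispersal rates are plausibility choices, not estimates from
any dataset.

What the generator does *not* emulate: group structure and male histories,
age-dependent dispersal, heaping or systematic bias in age estimates
(errors are symmetric by construction), juvenile mortality of the focal
females themselves, and environmental trends. Passing tests therefore
demonstrate correctness of the estimators under the stated sampling
mechanisms, not robustness to every feature of real field data.

`true_prr()` replays the same life-history model with *complete* observation
(every female followed birth to death, no censoring) on a very large cohort,
and pushes those complete lives through the same PrR computation. It is the
ground truth that estimates from truncated, censored cohorts must recover,
and the recovery is part of the acceptance tests (at 500 observed females the
estimate sits well within the Monte-Carlo spread of the truth, and increases
monotonically as the simulated cessation age falls).

## Numerical choices

* **Ties.** Deaths and censorings tied at one age: deaths are processed
  first (the censored female stays in the risk set), the standard
  counting-process convention.
* **Quantile crossing.** Within the crossing class the cumulative fecundity
  is linear (fecundity uniform within a class), so $B$ and $M$ interpolate
  linearly; quantile ages are clamped to the survivorship grid before
  integrating.
* **Denominator bias.** With the headcount denominator, a class in which
  many females exit contributes fractional person-years but whole heads, so
  $m(x)$ is biased low exactly where exits concentrate — at old ages. For
  estimating the fecundity schedule this mimics the verbatim definition
  ("births divided by females observed at that age"); for the type-I
  calibration experiment, where exchangeability of $m$ across classes is the
  point, the person-years denominator is used because it is mean-unbiased
  under a constant birth hazard.
* **Interval selection.** A completed interbirth interval is observed only
  if the mother survived it, so under appreciable adult mortality the
  completed-interval mean sits slightly below the generating mean (about
  0.1 y under the default mortality). The interval-recovery tests therefore
  run under negligible pre-senescent mortality; the effect itself is a
  property of real data, not an artifact.
* **Degenerate inputs.** Zero-length at-risk intervals are dropped with a
  warning (error if none remain); all-zero fecundity, single permutable
  classes, and $T(B) = 0$ raise informative errors rather than returning
  NaN.

## Problem sizes

The test suite and the acceptance script run everything at desk scale,
chosen as the smallest sizes at which the checked properties are sharp: 100
random complete cohorts for the survivorship oracle, 10,000 shuffles against
exhaustive enumeration on 5 permutable classes, 200 null cohorts of 150
females (1,000 shuffles each) for the size of the test, 8 replicate cohorts
of 500 females against a 20,000-life ground truth for recovery, and the
reference 25-female cohort with 10,000 shuffles and 1,000 uncertainty
iterations (1,000 shuffles inside each) for the headline run.

## Known limitations

Neither PrR nor the threshold criterion distinguishes menopause from other
causes of late-life sterility; the package quantifies post-reproductive
*lifespan*, not its physiological mechanism. The permutation null treats
age-class fecundity values as exchangeable, which heteroscedastic estimates
(sparse old-age classes) satisfy only approximately — the calibration
experiment bounds the practical consequence. Survivorship below the youngest
entry age is unidentifiable and everything downstream is, by design,
conditional on survival to that age.
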