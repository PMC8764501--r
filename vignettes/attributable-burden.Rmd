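---
title: "Methods: comparative risk assessment of alcohol-attributable cancer burden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative risk assessment of alcohol-attributable cancer burden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alcoburden)
```

## The model

`alcoburden` implements a comparative risk assessment: it contrasts the
observed population distribution of alcohol consumption with a
counterfactual in which nobody drinks, and attributes the corresponding
share of cancer deaths and disability-adjusted life years (DALYs) to
alcohol. The pipeline has five stages.

**Exposure.** Respondents of a quantity-frequency survey report their
habitual weekly — or, when drinking less than weekly, monthly — units of
beer, wine and spirits. One standard unit carries about 14 g of pure
ethanol in the Americas, so

$$\text{g/day} = \frac{(\text{beer} + \text{wine} + \text{spirits})
\times g_\text{unit}}{\text{days in the reporting period}},$$

with 7 days per week and 30.44 days (the mean Gregorian month) per
month. Each respondent is then classified as a non-drinker (0 g/day),
light (0.1–12.5), moderate (12.6–50) or heavy (> 50 g/day) drinker.
Prevalence per stratum is the ratio of summed sampling weights — the
design-weighted estimator — so it is invariant to rescaling all weights
by a constant.

**Relative risks.** Risks per cancer site, sex and exposed consumption
level come from meta-analytic estimates supplied as configuration. The
reference category is non-drinkers (including former drinkers; the
survey schema cannot distinguish them, and the reference group of the
source meta-analyses includes them too). Associations flagged as not
statistically significant are censored to RR = 1 before any
computation, and a missing table entry is likewise treated as RR = 1
(with a warning): absence of evidence is treated as no effect, never as
an error.

**Attributable fraction.** With $P_i$ the proportion at exposed level
$i$ and $RR_i$ its relative risk, the population attributable fraction
over the $n = 3$ exposed levels is

$$PAF = \frac{\sum_{i=1}^{n} P_i (RR_i - 1)}
{\sum_{i=1}^{n} P_i (RR_i - 1) + 1},$$

and its level-wise decomposition uses the shared denominator,
$PAF_i = P_i (RR_i - 1) / (\sum_j P_j (RR_j - 1) + 1)$. This is the only
decomposition whose terms sum exactly to the total, which is what makes
per-level attributable counts additive across a report table. PAFs are
computed per sex only: the relative risks are sex-specific and the
exposure distribution entering the formula is the sex-level one. Age
enters later, through age-specific death counts and residual life
expectancy. Protective risks (RR < 1) are permitted by the engine and
contribute negatively, although the shipped cancer configuration never
produces one after censoring.

**Burden accounting.** Registry records missing sex and/or age are
excluded (and counted); records are mapped to sites by the
three-character ICD-10 category, with ranges such as C18–C20 expanded;
codes outside the configured sites are tallied and ignored. Then, per
site, sex and age band:

* YLL = deaths × residual life expectancy at the band (read at the
  band, not interpolated — the computation works per age category
  throughout);
* YLD = population × Σ over the four cancer sequelae (diagnosis and
  primary therapy, controlled, metastatic, terminal) of sequela
  prevalence × disability weight, each weight in (0, 1);
* DALY = YLL + YLD, exactly;
* attributable X = X × PAF(site, sex), for every measure, total and per
  level. The same PAF is applied to mortality and morbidity, and to
  every age band.

All attributable quantities are kept as reals; rounding to integers and
whole percents happens only in `render_burden_table()`. This is why a
rendered total can differ by one unit from the sum of its rendered
rows — the sums are exact before display rounding, and the tests assert
them there.

**Scenarios.** A counterfactual shift moves the entire baseline mass of
one or more categories into lower categories, simultaneously (under the
combined preset, moderate→light and heavy→moderate, the moderate class
ends up holding exactly the baseline heavy mass). PAFs and burden are
recomputed under the shifted prevalence with observed deaths held
fixed; prevented burden is baseline minus counterfactual attributable
burden. Shifted drinkers adopt the destination category's RR wholesale;
no within-category dose modelling is attempted, which is the only
reading consistent with categorical scenario definitions. Because the
numerator drops of the single shifts add and the denominator shrinks,
this model is necessarily superadditive: the combined scenario always
prevents at least as much as either single shift, a property the test
suite checks on random configurations.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `grams_per_unit` | 14 | g ethanol | standard unit content in the Americas; varies by country, hence a parameter |
| `monthly_divisor` | 30.44 | days | mean Gregorian month; any fixed convention works, this one is unbiased over years |
| category breaks | 12.5, 50 | g/day | boundaries of the meta-analytic consumption levels |
| `missingness_rate` | 0.007 | fraction | share of registry records with missing demographics, matching the emulated registry year |
| `nontarget_rate` | 0.10 | fraction | filler causes of death mixed in so ICD filtering is genuinely exercised |
| `extended` | `FALSE` | — | adds melanoma (C43), pancreas (C25), prostate (C61) for the sensitivity analysis |

The category boundaries are implemented as half-open intervals
(0, 12.5], (12.5, 50], (50, ∞): the nominal 12.5–12.6 gap in the level
definitions is closed by assigning exactly 12.5 g/day to light, because
continuous g/day values need a total classification.

## The synthetic-data generator

No real microdata ship with the package. A `ground_truth()` object
fixes the true per-sex consumption distribution, baseline (non-drinker)
death rates per site × sex × age band, population counts, a registry
missingness rate and a seed; every generator is a deterministic
function of that seed, and generator RNG never leaks into the caller's
stream.

* `generate_survey()` draws sex and age from the population counts,
  assigns each respondent a true category, then draws a g/day value
  strictly interior to the category band and converts it back into
  beer/wine/spirits unit counts (random beverage split). Interior draws
  mean the round trip through unit arithmetic can never cross a
  category boundary, so generated records always classify into the
  category they were drawn for. Weights are stratum inverse sampling
  probabilities times mean-one lognormal noise (sd 0.3 on the log
  scale): noisy enough that an unweighted estimator is visibly wrong,
  while independent of category so the weighted estimator stays
  unbiased.
* `generate_registry()` draws Poisson death counts around baseline rate
  × population × the exposure inflation factor
  $1 + \sum_i P_i(RR_i - 1)$. By construction the analytic PAF is the
  expected attributable fraction in the registry, which is what lets an
  end-to-end run recover the published attributable-fraction structure.
* `generate_life_table()` is a stylized WHO-like table: strictly
  decreasing residual life expectancy from ~52 years in the youngest
  adult band to ~9.5 at 70+, giving roughly 17 years of life lost per
  cancer death under the default age gradient of mortality.
* `generate_yld_table()` scales the four sequela prevalences with the
  local mortality rate (stylized phase durations of 0.5, 3, 0.3 and
  0.1 years) and uses GBD-style cancer disability weights (0.288,
  0.049, 0.451, 0.540). YLD comes out near 3% of YLL, as expected for
  largely fatal cancers.

The default calibration (`default_ground_truth()`) reproduces the
published Argentine 2018 marginals: 66% of men and 42% of women drink,
19%/7.2% moderately and 4.5%/0.5% heavily, about 53% of adults overall;
site × sex death totals are set to the national scale implied by the
published attributable counts and fractions. Because the genuine
meta-analytic RRs live in supplementary material that is not
redistributed here, the shipped RR table (`rr_synthetic.yaml`) is
synthetic: back-calculated from the published sex-level prevalences and
per-level attributable fractions, with significance flags mirroring the
published zero cells (colorectal cancer in women entirely
non-significant, liver cancer heavy-only, breast cancer inapplicable to
men). A default end-to-end run therefore lands close to the published
headline figures (~1,400 attributable deaths, ~24,000 attributable
DALYs, half of both in the moderate category) without containing any
real survey, registry or meta-analysis record.

What the generator deliberately does **not** emulate: the joint
distribution of the real survey (beverage preferences, response
heaping, top-coding), drinking trajectories over time, unrecorded
consumption, binge patterns, exposure time lags, and uncertainty in the
RRs. Passing tests therefore demonstrate that the estimators and
accounting are correct under the stated model — not that the synthetic
numbers are themselves national estimates.

## The micro-simulation oracle

`simulate_cohort_deaths()` validates the PAF engine without sharing any
code with it. Each simulated person dies with probability
$b \cdot RR$ of their level; factual deaths are generated as
counterfactual (baseline-risk) deaths plus excess deaths through an
exact nested-binomial decomposition,
$b + (1-b)\,\frac{b(RR-1)}{1-b} = b \cdot RR$ (for protective levels,
factual deaths are a thinning of counterfactual ones). The coupling
through common randomness makes the empirical excess fraction
$(D - D_{cf})/D$ a low-variance unbiased estimator of the analytic PAF;
its delta-method standard error treats excess and counterfactual deaths
as independent Poisson-like counts. The worked configuration
$P = (0.5, 0.2, 0.1)$, $RR = (1.2, 2.0, 4.0)$ has
$PAF = 0.6/1.6 = 0.375$ analytically, and the simulation at
$n = 2{,}000{,}000$ agrees to within 0.01:

```{r oracle}
sim <- simulate_cohort_deaths(c(0.5, 0.2, 0.1), c(1.2, 2.0, 4.0),
                              baseline_risk = 0.01, n = 2e6, seed = 1)
empirical_paf(sim)
paf_total(c(0.5, 0.2, 0.1), c(1.2, 2.0, 4.0))
```

## Numerical choices and degenerate inputs

* Level decomposition identity is exact to 1e-12 and tested on random
  configurations; prevalence validation allows a 1e-12 slack on the
  sum-to-one constraint to absorb float noise from upstream ratios.
* Exactly 0 g/day is a non-drinker; any positive amount classifies into
  an exposed level.
* An empty survey stratum is dropped with a warning, never reported as
  a silent zero; a stratum with deaths but no PAF, a death band without
  a life-table entry, and a breast × male lookup are hard errors.
* A registry age below 18 (possible only in user-supplied data) is
  folded into the 18–29 band rather than dropped.
* Scenario shifts may target `non_drinker` (full abstention prevents
  exactly 100% of the attributable burden, the PAF's defining
  property); shifts towards a higher category are rejected.
* `ground_truth()` enforces per-sex proportions summing to 1 (1e-12),
  rates and proportions in [0, 1], and integer population counts.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic
data: surveys of 4,000–50,000 respondents (50,000 for the
prevalence-recovery check, where the ±1 percentage-point criterion
sits at about three standard errors of the weighted estimator),
registries of roughly 19,000–100,000 records, micro-simulation cohorts
of 2,000,000 people for the PAF oracle (20 random configurations plus
the worked case), and 1,000 random configurations for the
decomposition identity. The analysis scripts use the national scale
throughout: 29,224 respondents and a full-size registry.

## Known limitations

* Point estimates only: no uncertainty intervals for PAFs or burden,
  and no variance estimation for the complex survey design beyond the
  weighted point estimator.
* The same PAF is applied to deaths, YLLs and YLDs, and to every age
  band; age-specific exposure feeds the generator but not the
  attribution.
* The shipped RR table is a calibration stand-in, not the meta-analytic
  evidence; substantive applications must supply their own
  configuration via `read_rr_config()`.
* Scenario results describe the categorical model stated above;
  policies that move people part-way within a category are outside its
  resolution.
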