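# alcoburden

Comparative risk assessment of the alcohol-attributable burden of
cancer, modelled on the 2018 Argentine national estimates.

Alcohol causally raises the risk of at least six cancers — oral cavity
and pharynx (ICD-10 C00–C14), esophagus (C15), colorectal (C18–C20),
liver (C22), larynx (C32) and female breast (C50). `alcoburden` is for
epidemiologists and burden-of-disease analysts who want a tested,
fully reproducible pipeline from survey microdata to attributable
burden: it converts beverage-specific quantity-frequency responses
into grams of ethanol per day, estimates survey-weighted prevalence of
four consumption levels (non-drinker, light 0.1–12.5 g/day, moderate
12.6–50, heavy > 50), combines them with site- and sex-specific
relative risks into multi-level population attributable fractions

$$PAF = \frac{\sum_{i=1}^{n} P_i\,(RR_i - 1)}{\sum_{i=1}^{n} P_i\,(RR_i - 1) + 1},$$

multiplies ICD-10 coded registry deaths, years of life lost
(YLL = deaths × residual life expectancy) and years lived with
disability (YLD = sequela prevalence × disability weight, over four
cancer phases) by those fractions, and evaluates counterfactual
consumption-shift scenarios (heavy→moderate, moderate→light, both,
full abstention).

Because the real inputs (national survey, vital registration, GBD YLD
tables, meta-analytic relative risks) cannot be redistributed, the
package ships a synthetic-data generator with known ground truth,
calibrated to the published 2018 marginals, plus a cohort
micro-simulation that serves as an independent oracle for the PAF
estimator. Everything downstream is testable end to end without any
download; see `vignettes/attributable-burden.Rmd` for the methods and
their assumptions.

## Worked example

```r
library(alcoburden)
res <- run_pipeline(seed = 1)   # 29,224 respondents, full-size registry

res$prevalence[, 1:5]
#>   sex   non_drinker light moderate   heavy
#> 1 F           0.573 0.345   0.0764 0.00514
#> 2 M           0.343 0.418   0.190  0.0497
```

The survey-weighted prevalence recovers the calibrated truth (66% of
men and 42% of women drink; 19%/7.2% moderately, 4.5%/0.5% heavily).
The attributable fractions per site and sex, e.g. for esophageal
cancer:

```r
res$paf[res$paf$site == "esophagus", ]
#>   site      sex   paf_light paf_moderate paf_heavy paf_total
#> 1 esophagus M         0.107       0.206     0.154     0.468
#> 2 esophagus F         0           0.0735    0.0142    0.0877
```

— 47% of male esophageal-cancer deaths are attributable to alcohol,
and the level-wise fractions sum exactly to the total. Applying the
PAFs to the synthetic registry, life table and YLD inputs:

```r
sum(res$burden$deaths_attrib)   # 1441 of 17150 site deaths (8.4%)
sum(res$burden$daly_attrib)     # 24868
res$scenarios[, c("scenario", "prevented_deaths", "pct_deaths_prevented")]
#>   scenario          prevented_deaths pct_deaths_prevented
#> 1 heavy to moderate             251.                 17.4
#> 2 moderate to light             528.                 36.7
#> 3 combined                      843.                 58.5
#> 4 full abstention              1441.                100
```

Half of the attributable deaths (50%) sit in the *moderate* category:
the prevention paradox — the moderate group is far larger than the
heavy group — so shifting moderate drinkers to light drinking prevents
about twice as many deaths (37%) as shifting heavy drinkers to
moderate (17%), and full abstention by definition prevents 100% of the
attributable burden.

The same computation is available as a step-by-step narrative under
`analysis/` (`01_simulate.R` … `06_report.R`, writing their tables to
`results/`), and every stage is an exported function
(`grams_per_day()`, `weighted_prevalence()`, `paf_table()`,
`filter_and_group()`, `assemble_burden()`, `evaluate_scenario()`,
`render_burden_table()`) so real data in the documented CSV schemas
can be substituted for any synthetic input.

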