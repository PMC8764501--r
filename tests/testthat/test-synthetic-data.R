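test_that("generators are deterministic under a fixed seed", {
  truth <- fixture_truth(seed = 42L)
  expect_identical(generate_survey(truth, 500), generate_survey(truth, 500))
  expect_identical(generate_registry(truth), generate_registry(truth))
  expect_identical(generate_yld_table(truth), generate_yld_table(truth))
  other <- fixture_truth(seed = 43L)
  expect_false(identical(generate_survey(truth, 500),
                         generate_survey(other, 500)))
})

test_that("generator RNG does not leak into the caller's RNG stream", {
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(generate_survey(fixture_truth(), 50))
  expect_identical(runif(1), before)
})

test_that("survey g/day always classifies into the assigned category", {
  truth <- fixture_truth(seed = 5L)
  survey <- generate_survey(truth, 4000)
  got <- as.character(categorize_consumption(grams_per_day(survey)))
  expect_identical(got, attr(survey, "true_level"))
})

test_that("an all-non-drinker truth yields zero units everywhere", {
  truth <- fixture_truth()
  truth$prevalence[, consumption_levels()] <-
    tibble::tibble(non_drinker = c(1, 1), light = 0, moderate = 0, heavy = 0)
  survey <- generate_survey(truth, 300)
  expect_true(all(survey$beer_units == 0 & survey$wine_units == 0 &
                    survey$spirits_units == 0))
})

test_that("survey weights are positive and ages/sexes follow the population", {
  truth <- fixture_truth(seed = 9L)
  survey <- generate_survey(truth, 5000)
  expect_true(all(survey$weight > 0))
  expect_true(all(survey$age >= 18))
  expect_setequal(unique(survey$sex), c("M", "F"))
  # younger bands hold more population, so should dominate the sample
  bands <- table(age_to_band(survey$age))
  expect_gt(bands[["18-29"]], bands[["70+"]])
})

test_that("the downstream estimator recovers the generating prevalence", {
  truth <- fixture_truth(seed = 31L)
  survey <- generate_survey(truth, 20000)
  prev <- weighted_prevalence(survey)
  for (s in c("M", "F")) {
    truth_p <- as.numeric(truth$prevalence[truth$prevalence$sex == s,
                                           consumption_levels()])
    est_p <- as.numeric(prev[prev$sex == s, consumption_levels()])
    expect_true(all(abs(est_p - truth_p) < 0.015))
  }
})

test_that("registry missingness matches the configured rate", {
  truth <- fixture_truth(seed = 77L, missingness_rate = 0.007)
  # inflate rates to get a registry of ~100k records
  truth$baseline_death_rate$rate <- pmin(truth$baseline_death_rate$rate * 130, 0.5)
  registry <- generate_registry(truth)
  expect_gt(nrow(registry), 50000)
  blank <- mean(is.na(registry$sex) | is.na(registry$age))
  expect_lt(abs(blank - 0.007), 0.002)
})

test_that("zero baseline rates give an empty registry for target sites", {
  truth <- fixture_truth()
  truth$baseline_death_rate$rate <- 0
  registry <- generate_registry(truth)
  expect_equal(nrow(registry), 0)
})

test_that("breast-cancer records are generated for women only", {
  truth <- fixture_truth(seed = 13L)
  registry <- generate_registry(truth)
  breast <- registry[!is.na(registry$icd10) &
                       substr(registry$icd10, 1, 3) == "C50", ]
  expect_gt(nrow(breast), 0)
  expect_true(all(breast$sex == "F" | is.na(breast$sex)))
})

test_that("the registry mixes in non-target causes at the configured rate", {
  truth <- fixture_truth(seed = 21L, nontarget_rate = 0.10)
  truth$baseline_death_rate$rate <- pmin(truth$baseline_death_rate$rate * 30, 0.5)
  registry <- generate_registry(truth)
  sites <- cancer_sites(extended = TRUE)
  frac <- mean(is.na(icd10_to_site(registry$icd10, sites)))
  expect_lt(abs(frac - 0.10), 0.02)
})

test_that("the life table decreases strictly with age", {
  lt <- generate_life_table()
  expect_equal(lt$age_band, age_bands())
  expect_true(all(diff(lt$life_expectancy_years) < 0))
  expect_lt(lt$life_expectancy_years[6], lt$life_expectancy_years[1])
  expect_true(all(lt$life_expectancy_years > 0))
  expect_error(generate_life_table(max_age = -1), "positive")
})

test_that("YLD inputs have valid prevalences and disability weights", {
  truth <- fixture_truth(seed = 3L)
  yld_in <- generate_yld_table(truth)
  prev_cols <- paste0("prev_", c("diagnosis", "controlled", "metastatic",
                                 "terminal"))
  dw_cols <- paste0("dw_", c("diagnosis", "controlled", "metastatic",
                             "terminal"))
  expect_true(all(as.matrix(yld_in[prev_cols]) >= 0 &
                    as.matrix(yld_in[prev_cols]) <= 1))
  expect_true(all(as.matrix(yld_in[dw_cols]) > 0 &
                    as.matrix(yld_in[dw_cols]) < 1))
  # zero sequela prevalence propagates to zero YLD downstream
  yld_in[prev_cols] <- 0
  expect_true(all(compute_yld(yld_in)$yld == 0))
})

test_that("cohort simulation handles the degenerate and invalid cases", {
  sim0 <- simulate_cohort_deaths(c(0, 0, 0), c(1.2, 2, 4), 0.01, 1e4, seed = 2)
  expect_equal(sum(sim0$deaths) - sum(sim0$deaths_counterfactual), 0)
  sim1 <- simulate_cohort_deaths(c(0.5, 0.2, 0.1), c(1, 1, 1), 0.01, 5e5,
                                 seed = 3)
  est <- empirical_paf(sim1)
  expect_lt(abs(est$estimate), 3 * max(est$se, 1e-6))
  expect_error(simulate_cohort_deaths(c(0.5, 0.2, 0.1), c(1, 2, 150), 0.01,
                                      1e4, seed = 1),
               "not a probability")
  expect_warning(empirical_paf(simulate_cohort_deaths(c(0.1, 0.1, 0.1),
                                                      c(1, 1, 1), 0, 100,
                                                      seed = 1)),
                 "no deaths")
})

test_that("protective relative risks thin the counterfactual deaths", {
  sim <- simulate_cohort_deaths(c(0.8), c(0.5), 0.02, 1e6, seed = 8)
  est <- empirical_paf(sim)
  analytic <- paf_total(c(0.8), c(0.5))
  expect_lt(abs(est$estimate - analytic), 3 * est$se)
  expect_lt(est$estimate, 0)
})

test_that("ground-truth validation catches inconsistent inputs", {
  truth <- fixture_truth()
  bad <- truth
  bad$prevalence$light[1] <- bad$prevalence$light[1] + 0.01
  expect_error(validate_ground_truth(bad), "sum to 1")
  bad2 <- truth
  bad2$missingness_rate <- 1.5
  expect_error(validate_ground_truth(bad2), "\\[0, 1\\]")
  expect_error(generate_survey(truth, 0), "positive count")
})

test_that("the default ground truth is calibrated to the survey marginals", {
  truth <- default_ground_truth()
  p <- truth$prevalence
  expect_equal(1 - p$non_drinker[p$sex == "M"], 0.66)
  expect_equal(p$heavy[p$sex == "M"], 0.045)
  expect_equal(p$moderate[p$sex == "M"], 0.19)
  expect_equal(1 - p$non_drinker[p$sex == "F"], 0.42)
  expect_equal(p$moderate[p$sex == "F"], 0.072)
  expect_equal(p$heavy[p$sex == "F"], 0.005)
  # overall drinking prevalence ~53% with the population sex mix
  pop <- truth$population_counts |> dplyr::count(sex, wt = population)
  drinkers <- sum((1 - p$non_drinker[match(pop$sex, p$sex)]) * pop$n) / sum(pop$n)
  expect_lt(abs(drinkers - 0.53), 0.01)
})
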