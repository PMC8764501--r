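tiny_registry <- function() {
  tibble::tibble(
    record_id = sprintf("D%02d", 1:8),
    icd10 = c("C15", "C19", "J18", "C15", "C50", "bad", "C50", "C22"),
    sex = c("M", "F", "M", "M", "F", "M", "M", NA),
    age = c(63, NA, 70, 45, 55, 50, 60, 40),
    year = 2018
  )
}

test_that("filter_and_group applies the cleaning rules and reconciles", {
  expect_warning(got <- filter_and_group(tiny_registry()), "malformed")
  deaths <- got$deaths
  # C15/M/63 lands in esophagus, men, 60-69
  expect_equal(deaths$deaths[deaths$site == "esophagus" &
                               deaths$age_band == "60-69"], 1)
  # C19/F with missing age is excluded and counted
  expect_equal(got$exclusions$n_missing, 2)  # one NA age, one NA sex
  # J18 is ignored as non-target; C50/M is a target code for the wrong sex
  expect_equal(got$exclusions$n_nontarget, 1)
  expect_equal(got$exclusions$n_inapplicable_sex, 1)
  expect_equal(got$exclusions$n_malformed, 1)
  ex <- got$exclusions
  expect_equal(ex$n_malformed + ex$n_missing + ex$n_ignored + ex$n_grouped,
               ex$n_input)
  expect_false(any(deaths$site == "breast" & deaths$sex == "M"))
})

test_that("attributable deaths scale linearly with the PAF", {
  deaths <- tibble::tibble(site = "esophagus", sex = "M",
                           age_band = "60-69", deaths = 100)
  paf <- tibble::tibble(site = "esophagus", sex = "M",
                        paf_light = 0.02, paf_moderate = 0.03,
                        paf_heavy = 0.02, paf_total = 0.07, n_levels = 3L)
  got <- attributable_deaths(deaths, paf)
  expect_equal(got$deaths_attrib, 7)
  expect_equal(got$deaths_attrib_light + got$deaths_attrib_moderate +
                 got$deaths_attrib_heavy, 7)
  paf0 <- paf; paf0[, c("paf_light", "paf_moderate", "paf_heavy",
                        "paf_total")] <- 0
  expect_equal(attributable_deaths(deaths, paf0)$deaths_attrib, 0)
  expect_error(attributable_deaths(deaths, paf[0, ]), "no PAF available")
})

test_that("YLL is deaths times residual life expectancy, linearly", {
  lt <- tibble::tibble(age_band = "60-69", life_expectancy_years = 20)
  deaths <- tibble::tibble(site = "x", sex = "M", age_band = "60-69",
                           deaths = 10)
  expect_equal(compute_yll(deaths, lt)$yll, 200)
  deaths$deaths <- 0
  expect_equal(compute_yll(deaths, lt)$yll, 0)
  deaths$deaths <- 20
  expect_equal(compute_yll(deaths, lt)$yll, 400)  # doubling doubles
  deaths$age_band <- "70+"
  expect_error(compute_yll(deaths, lt), "no life-table entry")
})

test_that("YLD sums sequela prevalence times disability weight", {
  yld_in <- tibble::tibble(
    site = "x", sex = "F", age_band = "50-59",
    prev_diagnosis = 0.001, prev_controlled = 0, prev_metastatic = 0,
    prev_terminal = 0,
    dw_diagnosis = 0.3, dw_controlled = 0.049, dw_metastatic = 0.451,
    dw_terminal = 0.54,
    population = 1000
  )
  expect_equal(compute_yld(yld_in)$yld, 0.3)
  # permuting the sequelae leaves the result unchanged
  perm <- yld_in
  perm[, c("prev_diagnosis", "prev_terminal")] <-
    yld_in[, c("prev_terminal", "prev_diagnosis")]
  perm[, c("dw_diagnosis", "dw_terminal")] <-
    yld_in[, c("dw_terminal", "dw_diagnosis")]
  expect_equal(compute_yld(perm)$yld, compute_yld(yld_in)$yld)
  bad <- yld_in; bad$dw_controlled <- 1
  expect_error(compute_yld(bad), "\\(0, 1\\)")
})

test_that("assembled burden satisfies the accounting identities", {
  truth <- fixture_truth(seed = 19L)
  survey <- generate_survey(truth, 8000)
  registry <- generate_registry(truth)
  prev <- weighted_prevalence(survey)
  sites <- cancer_sites()
  paf <- paf_table(prev, truth$rr, sites)
  grouped <- filter_and_group(registry, sites)
  yld_in <- generate_yld_table(truth)
  burden <- assemble_burden(grouped$deaths, fixture_life_table(), yld_in, paf)

  expect_equal(burden$daly_total, burden$yll_total + burden$yld_total)
  expect_equal(burden$daly_attrib, burden$yll_attrib + burden$yld_attrib,
               tolerance = 1e-9)
  for (m in c("deaths", "yll", "yld", "daly")) {
    lv <- rowSums(burden[paste0(m, "_attrib_", exposed_levels())])
    expect_equal(lv, burden[[paste0(m, "_attrib")]], tolerance = 1e-12)
  }
  expect_true(all(burden$deaths_attrib >= 0))
  expect_true(all(burden$deaths_attrib <= burden$deaths_total))

  # aggregates equal the sum of their strata
  agg <- aggregate_burden(burden, by = c("site", "sex"))
  expect_equal(sum(agg$daly_attrib), sum(burden$daly_attrib))
  agg_sex <- aggregate_burden(burden, by = "sex")
  expect_equal(sort(agg_sex$deaths_total),
               sort(tapply(burden$deaths_total, burden$sex, sum) |> as.numeric()))
})

test_that("a stratum with burden but no PAF is a hard failure", {
  deaths <- tibble::tibble(site = "esophagus", sex = "F",
                           age_band = "60-69", deaths = 5)
  paf <- tibble::tibble(site = "esophagus", sex = "M", paf_light = 0,
                        paf_moderate = 0, paf_heavy = 0, paf_total = 0,
                        n_levels = 3L)
  yld_in <- generate_yld_table(fixture_truth())[0, ]
  expect_error(assemble_burden(deaths, fixture_life_table(), yld_in, paf),
               "missing PAF")
})
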