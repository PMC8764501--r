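make_record <- function(beer = 0, wine = 0, spirits = 0, freq = "week",
                        sex = "M", age = 40, weight = 1) {
  tibble::tibble(sex = sex, age = age, weight = weight,
                 beer_units = beer, wine_units = wine, spirits_units = spirits,
                 freq_unit = freq)
}

test_that("grams_per_day converts quantity-frequency responses correctly", {
  expect_equal(grams_per_day(make_record(beer = 7)), 14)
  expect_equal(grams_per_day(make_record()), 0)
  expect_equal(grams_per_day(make_record(wine = 30, freq = "month")),
               30 * 14 / 30.44, tolerance = 1e-12)
  expect_lt(abs(grams_per_day(make_record(wine = 30, freq = "month")) - 13.80),
            0.01)
  # mixed beverages add up; grams_per_unit scales linearly
  expect_equal(grams_per_day(make_record(beer = 2, wine = 3, spirits = 2)),
               14)
  expect_equal(grams_per_day(make_record(beer = 7), grams_per_unit = 10), 10)
})

test_that("grams_per_day rejects invalid inputs", {
  expect_error(grams_per_day(make_record(beer = -1)), "non-negative")
  bad <- make_record(); bad$freq_unit <- "year"
  expect_error(grams_per_day(bad), "freq_unit")
  expect_error(grams_per_day(make_record(), grams_per_unit = 0), "positive")
})

test_that("categorize_consumption uses the half-open category boundaries", {
  got <- categorize_consumption(c(0, 0.1, 12.5, 12.6, 50, 50.0001, 56))
  expect_equal(as.character(got),
               c("non_drinker", "light", "light", "moderate", "moderate",
                 "heavy", "heavy"))
  expect_true(is.ordered(got))
  expect_error(categorize_consumption(-1), "non-negative")
})

test_that("categorization of g/day is monotone in each beverage count", {
  base <- make_record(beer = 2, wine = 1, spirits = 0)
  for (col in c("beer_units", "wine_units", "spirits_units")) {
    recs <- base[rep(1, 30), ]
    recs[[col]] <- seq(0, 60, length.out = 30)
    cats <- as.integer(categorize_consumption(grams_per_day(recs)))
    expect_true(all(diff(cats) >= 0))
  }
})

test_that("weighted_prevalence matches the hand-computed weighted average", {
  survey <- tibble::tibble(
    sex = "M", age = c(30, 40), weight = c(1, 3),
    beer_units = c(2, 0), wine_units = 0, spirits_units = 0,
    freq_unit = "week"
  )
  expect_warning(prev <- weighted_prevalence(survey), "empty")  # no women
  expect_equal(prev$light, 0.25)
  expect_equal(prev$non_drinker, 0.75)
  expect_equal(prev$n, 2L)
})

test_that("equal weights reduce to unweighted proportions", {
  set.seed(11)
  survey <- tibble::tibble(
    sex = sample(c("M", "F"), 400, TRUE), age = sample(18:80, 400, TRUE),
    weight = 2.5,
    beer_units = sample(0:40, 400, TRUE), wine_units = 0, spirits_units = 0,
    freq_unit = "week"
  )
  prev <- weighted_prevalence(survey)
  raw <- table(survey$sex,
               categorize_consumption(grams_per_day(survey)))
  for (s in c("M", "F")) {
    expect_equal(as.numeric(prev[prev$sex == s, consumption_levels()]),
                 as.numeric(raw[s, ] / sum(raw[s, ])))
  }
})

test_that("prevalence is invariant to rescaling weights and sums to one", {
  set.seed(12)
  survey <- tibble::tibble(
    sex = sample(c("M", "F"), 500, TRUE), age = sample(18:85, 500, TRUE),
    weight = stats::rlnorm(500),
    beer_units = stats::rpois(500, 4), wine_units = stats::rpois(500, 2),
    spirits_units = 0, freq_unit = sample(c("week", "month"), 500, TRUE)
  )
  p1 <- weighted_prevalence(survey, by = c("sex", "age_band"))
  survey2 <- survey; survey2$weight <- survey2$weight * 17.3
  p2 <- weighted_prevalence(survey2, by = c("sex", "age_band"))
  expect_equal(p1[consumption_levels()], p2[consumption_levels()],
               tolerance = 1e-12)
  expect_true(all(abs(rowSums(p1[consumption_levels()]) - 1) < 1e-9))
})

test_that("empty strata are dropped with a warning, not silently zeroed", {
  survey <- tibble::tibble(
    sex = "M", age = c(25, 27, 33), weight = 1,
    beer_units = 1, wine_units = 0, spirits_units = 0, freq_unit = "week"
  )
  expect_warning(prev <- weighted_prevalence(survey, by = c("sex", "age_band")),
                 "empty")
  expect_equal(nrow(prev), 2)  # only the observed strata are reported
})
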