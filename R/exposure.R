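# Exposure module: quantity-frequency responses -> g ethanol/day ->
# consumption category -> survey-weighted prevalence.

DAYS_PER_WEEK <- 7
DAYS_PER_MONTH <- 30.44  # mean Gregorian month; configurable in each function

validate_survey <- function(survey) {
  assert_columns(survey,
                 c("sex", "age", "weight",
                   "beer_units", "wine_units", "spirits_units", "freq_unit"),
                 "survey data")
  units <- c(survey$beer_units, survey$wine_units, survey$spirits_units)
  assert_that(!anyNA(units) && all(units >= 0),
              "beverage unit counts must be non-negative and non-missing")
  assert_that(all(survey$freq_unit %in% c("week", "month")),
              "freq_unit must be 'week' or 'month'")
  assert_that(all(survey$weight > 0), "sampling weights must be positive")
  assert_that(all(survey$sex %in% sex_codes()), "sex must be 'M' or 'F'")
  assert_that(all(survey$age >= 18), "survey respondents must be adults (age >= 18)")
  invisible(survey)
}

#' Convert quantity-frequency responses to grams of ethanol per day
#'
#' Sums the reported beer, wine and spirits standard units over the
#' reporting period (weekly, or monthly for less-than-weekly drinkers),
#' multiplies by the ethanol content of one standard unit, and divides by
#' the length of the period in days. A standard unit in the Americas
#' contains approximately 14 g of pure ethanol.
#'
#' @param survey Data frame of survey records with columns `beer_units`,
#'   `wine_units`, `spirits_units` (non-negative reals) and `freq_unit`
#'   (`"week"` or `"month"`), plus `sex`, `age`, `weight`.
#' @param grams_per_unit Grams of ethanol per standard unit (default 14).
#' @param monthly_divisor Days per month used for monthly reporters
#'   (default 30.44, the mean Gregorian month).
#' @return Numeric vector of grams of ethanol per day, one per record.
#' @examples
#' rec <- tibble::tibble(sex = "M", age = 40, weight = 1,
#'                       beer_units = 7, wine_units = 0, spirits_units = 0,
#'                       freq_unit = "week")
#' grams_per_day(rec)  # 7 units/week * 14 g / 7 days = 14 g/day
#' @export
grams_per_day <- function(survey, grams_per_unit = 14,
                          monthly_divisor = DAYS_PER_MONTH) {
  validate_survey(survey)
  assert_that(is.numeric(grams_per_unit) && grams_per_unit > 0,
              "grams_per_unit must be a positive number")
  assert_that(is.numeric(monthly_divisor) && monthly_divisor > 0,
              "monthly_divisor must be a positive number")
  units <- survey$beer_units + survey$wine_units + survey$spirits_units
  days <- ifelse(survey$freq_unit == "week", DAYS_PER_WEEK, monthly_divisor)
  units * grams_per_unit / days
}

#' Classify grams-per-day into a consumption category
#'
#' Exactly 0 g/day is a non-drinker; (0, 12.5] light; (12.5, 50] moderate;
#' above 50 heavy. The half-open intervals give every non-negative real a
#' category: the nominal gap between 12.5 and 12.6 g/day is closed by
#' assigning exactly 12.5 to light and anything above it to moderate.
#'
#' @param gpd Numeric vector of grams of ethanol per day (non-negative).
#' @param breaks Two increasing positive cut points, default `c(12.5, 50)`.
#' @return Ordered factor with levels [consumption_levels()].
#' @examples
#' categorize_consumption(c(0, 12.5, 12.6, 56))
#' @export
categorize_consumption <- function(gpd, breaks = c(12.5, 50)) {
  assert_that(is.numeric(gpd) && !anyNA(gpd) && all(gpd >= 0),
              "g/day values must be non-negative and non-missing")
  assert_that(length(breaks) == 2 && breaks[1] > 0 && breaks[2] > breaks[1],
              "breaks must be two increasing positive cut points")
  idx <- findInterval(gpd, c(0, breaks), left.open = TRUE) + 1L
  # findInterval with left.open: 0 -> 0 -> level 1; (0,12.5] -> 1; etc.
  factor(consumption_levels()[idx], levels = consumption_levels(),
         ordered = TRUE)
}

#' Survey-weighted prevalence of consumption categories
#'
#' Computes, within each stratum, the weighted proportion of respondents in
#' each consumption category: the sum of sampling weights of respondents in
#' the category divided by the sum of weights in the stratum. This accounts
#' for the complex survey design exactly as a Horvitz-Thompson ratio
#' estimator; proportions are invariant to rescaling all weights.
#'
#' @param survey Survey data frame (see [grams_per_day()] for the schema).
#' @param by Stratification columns: `"sex"` (default) or
#'   `c("sex", "age_band")`. An `age_band` column is derived from `age`.
#' @param grams_per_unit,monthly_divisor Passed to [grams_per_day()].
#' @return A tibble with one row per stratum: the `by` columns, one
#'   proportion column per consumption level, the unweighted count `n`, and
#'   `n_eff`, the Kish effective sample size \eqn{(\sum w)^2 / \sum w^2}.
#'   Strata of the full sex-by-band grid with no respondents are dropped
#'   with a warning. Proportions sum to 1 within every reported stratum.
#' @export
weighted_prevalence <- function(survey, by = "sex", grams_per_unit = 14,
                                monthly_divisor = DAYS_PER_MONTH) {
  assert_that(all(by %in% c("sex", "age_band")),
              "`by` may only contain 'sex' and 'age_band'")
  assert_that(nrow(survey) > 0, "survey has no records")
  validate_survey(survey)
  gpd <- grams_per_day(survey, grams_per_unit, monthly_divisor)
  dat <- tibble(
    level = categorize_consumption(gpd),
    weight = survey$weight,
    sex = survey$sex
  )
  if ("age_band" %in% by) dat$age_band <- age_to_band(survey$age)

  totals <- dat |>
    group_by(across(all_of(by))) |>
    summarise(w_total = sum(.data$weight),
              n = n(),
              n_eff = sum(.data$weight)^2 / sum(.data$weight^2),
              .groups = "drop")

  grid <- expand.grid(sex = sex_codes(),
                      age_band = if ("age_band" %in% by) age_bands() else NA,
                      stringsAsFactors = FALSE)[, by, drop = FALSE] |>
    unique()
  empty <- anti_join(grid, totals, by = by)
  if (nrow(empty) > 0) {
    warning(sprintf(
      "dropping %d empty stratum/strata: %s", nrow(empty),
      paste(apply(empty, 1, paste, collapse = "/"), collapse = ", ")
    ), call. = FALSE)
  }

  dat |>
    group_by(across(all_of(by)), .data$level, .drop = FALSE) |>
    summarise(w = sum(.data$weight), .groups = "drop") |>
    inner_join(totals, by = by) |>
    mutate(p = .data$w / .data$w_total) |>
    select(all_of(by), "level", "p", "n", "n_eff") |>
    pivot_wider(names_from = "level", values_from = "p", values_fill = 0) |>
    select(all_of(by), all_of(consumption_levels()), "n", "n_eff") |>
    arrange(across(all_of(by)))
}

#' Extract the exposed-level prevalence vector for one stratum
#'
#' Convenience accessor used by the PAF engine: returns the proportions of
#' the three exposed levels (light, moderate, heavy) for a given sex from a
#' prevalence table produced by [weighted_prevalence()].
#'
#' @param prevalence A prevalence table stratified by sex.
#' @param sex `"M"` or `"F"`.
#' @return Named numeric vector of length 3.
#' @export
prevalence_vector <- function(prevalence, sex) {
  assert_columns(prevalence, c("sex", consumption_levels()), "prevalence table")
  row <- prevalence[prevalence$sex == sex, , drop = FALSE]
  assert_that(nrow(row) == 1,
              sprintf("prevalence table must have exactly one row for sex '%s'", sex))
  setNames(as.numeric(row[1, exposed_levels()]), exposed_levels())
}
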