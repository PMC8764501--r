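# Synthetic-data generators: survey, death registry, life table, YLD
# inputs, all driven by a single ground-truth object, plus a cohort
# micro-simulation used as an independent oracle for the PAF estimator.

#' Ground truth for the synthetic-data generators
#'
#' Bundles everything the generators need: the true consumption-level
#' distribution per sex, the relative-risk table, baseline (non-drinker)
#' death rates per site x sex x age band, adult population counts,
#' the fraction of registry records with missing demographics, and the
#' fraction of non-target (filler) causes of death.
#'
#' @param prevalence Tibble with columns `sex` and one proportion column
#'   per consumption level; proportions sum to 1 per sex.
#' @param rr An [rr_table()].
#' @param baseline_death_rate Tibble `site`, `sex`, `age_band`, `rate`:
#'   annual death probability among non-drinkers.
#' @param population_counts Tibble `sex`, `age_band`, `population`
#'   (non-negative integers).
#' @param missingness_rate Fraction of death records with age and/or sex
#'   blanked (default 0.007).
#' @param nontarget_rate Fraction of registry records carrying a
#'   non-target ICD-10 code (default 0.10), included so code filtering is
#'   exercised.
#' @param seed Integer seed making every generator deterministic.
#' @return A validated list of class `ground_truth`.
#' @export
ground_truth <- function(prevalence, rr, baseline_death_rate,
                         population_counts, missingness_rate = 0.007,
                         nontarget_rate = 0.10, seed = 1L) {
  truth <- structure(
    list(prevalence = as_tibble(prevalence), rr = rr_table(rr),
         baseline_death_rate = as_tibble(baseline_death_rate),
         population_counts = as_tibble(population_counts),
         missingness_rate = missingness_rate,
         nontarget_rate = nontarget_rate, seed = seed),
    class = "ground_truth")
  validate_ground_truth(truth)
}

#' @rdname ground_truth
#' @param truth Object to validate.
#' @export
validate_ground_truth <- function(truth) {
  assert_that(inherits(truth, "ground_truth"), "not a ground_truth object")
  prev <- truth$prevalence
  assert_columns(prev, c("sex", consumption_levels()), "ground-truth prevalence")
  pmat <- as.matrix(prev[, consumption_levels()])
  assert_probability(c(pmat), "consumption-level proportions")
  assert_that(all(abs(rowSums(pmat) - 1) < 1e-12),
              "per-sex consumption proportions must sum to 1")
  bdr <- truth$baseline_death_rate
  assert_columns(bdr, c("site", "sex", "age_band", "rate"), "baseline death rates")
  assert_probability(bdr$rate, "baseline death rates")
  pop <- truth$population_counts
  assert_columns(pop, c("sex", "age_band", "population"), "population counts")
  assert_that(all(pop$population >= 0) && all(pop$population == round(pop$population)),
              "population counts must be non-negative integers")
  assert_probability(truth$missingness_rate, "missingness_rate")
  assert_probability(truth$nontarget_rate, "nontarget_rate")
  assert_that(is.numeric(truth$seed) && length(truth$seed) == 1,
              "seed must be a single integer")
  truth
}

#' Default ground truth calibrated to the published 2018 marginals
#'
#' Consumption prevalence is calibrated to the published Argentine 2018
#' survey marginals (any drinking 66% in men and 42% in women; moderate
#' 19% / 7.2%; heavy 4.5% / 0.5%; about 53% of adults overall). Baseline
#' death rates are chosen so that expected site x sex death counts match
#' the national scale implied by the published attributable counts and
#' fractions, spread over age bands with a steep age gradient. All values
#' are overridable by constructing a [ground_truth()] directly.
#'
#' @param seed Integer seed (default 1).
#' @param extended Include the sensitivity-analysis sites in the registry
#'   (default FALSE).
#' @param missingness_rate,nontarget_rate See [ground_truth()].
#' @return A `ground_truth` object.
#' @export
default_ground_truth <- function(seed = 1L, extended = FALSE,
                                 missingness_rate = 0.007,
                                 nontarget_rate = 0.10) {
  prevalence <- tibble(
    sex = c("M", "F"),
    non_drinker = c(0.340, 0.580),
    light = c(0.425, 0.343),
    moderate = c(0.190, 0.072),
    heavy = c(0.045, 0.005)
  )
  # Adult (18+) population, stylized national scale, thousands rounded.
  band_shares <- c(0.26, 0.20, 0.17, 0.14, 0.12, 0.11)
  population_counts <- tibble(
    sex = rep(sex_codes(), each = length(age_bands())),
    age_band = rep(age_bands(), 2),
    population = c(round(15.6e6 * band_shares), round(16.8e6 * band_shares))
  )
  # Expected total deaths per site and sex at national scale.
  targets <- tibble(
    site = c("oral_pharynx", "esophagus", "colorectal", "liver", "larynx",
             "oral_pharynx", "esophagus", "colorectal", "liver", "larynx",
             "breast"),
    sex = c(rep("M", 5), rep("F", 6)),
    deaths = c(590, 1159, 3714, 967, 641,
               280, 575, 3000, 800, 133,
               5167)
  )
  if (extended) {
    targets <- bind_rows(targets, tibble(
      site = c("melanoma", "pancreas", "prostate", "melanoma", "pancreas"),
      sex = c("M", "M", "M", "F", "F"),
      deaths = c(330, 2500, 3700, 250, 2400)
    ))
  }
  # Steep age gradient of cancer mortality across the six bands.
  age_gradient <- tibble(age_band = age_bands(),
                         share = c(0.005, 0.02, 0.07, 0.17, 0.28, 0.455))
  rr <- censor_nonsignificant(default_rr_table())
  inflation <- function(site, sex) {
    p <- prevalence_vector(prevalence, sex)
    rrv <- vapply(exposed_levels(), function(lv) {
      hit <- rr$rr[rr$site == site & rr$sex == sex & rr$level == lv]
      if (length(hit) == 0) 1 else hit
    }, numeric(1))
    1 + sum(p * (rrv - 1))
  }
  baseline <- targets |>
    cross_join(age_gradient) |>
    inner_join(population_counts, by = c("sex", "age_band")) |>
    rowwise() |>
    mutate(rate = .data$deaths * .data$share /
             (.data$population * inflation(.data$site, .data$sex))) |>
    ungroup() |>
    select("site", "sex", "age_band", "rate")

  ground_truth(prevalence, default_rr_table(), baseline, population_counts,
               missingness_rate = missingness_rate,
               nontarget_rate = nontarget_rate, seed = seed)
}

#' Generate a synthetic quantity-frequency survey
#'
#' Respondents are drawn with sex and age from the ground-truth population
#' counts, assigned a true consumption category from the per-sex
#' distribution, and given beverage-specific unit counts whose implied
#' grams-per-day fall strictly inside the assigned category. Drinkers
#' consuming less than one unit a week report monthly totals, all others
#' weekly. Sampling weights are stratum inverse sampling probabilities
#' with multiplicative lognormal noise (mean 1), so the weighted estimator
#' is exercised nontrivially while remaining unbiased.
#'
#' @param truth A [ground_truth()].
#' @param n_respondents Number of respondents (>= 1).
#' @param grams_per_unit Grams of ethanol per standard unit (default 14).
#' @return Tibble with the survey CSV schema: `respondent_id`, `sex`,
#'   `age`, `weight`, `beer_units`, `wine_units`, `spirits_units`,
#'   `freq_unit`.
#' @export
generate_survey <- function(truth, n_respondents, grams_per_unit = 14) {
  validate_ground_truth(truth)
  assert_that(is.numeric(n_respondents) && length(n_respondents) == 1 &&
                n_respondents >= 1,
              "n_respondents must be a positive count")
  n <- as.integer(n_respondents)
  with_seed(truth$seed + 101L, {
    pop <- truth$population_counts
    stratum <- sample.int(nrow(pop), n, replace = TRUE,
                          prob = pop$population / sum(pop$population))
    sex <- pop$sex[stratum]
    age <- draw_age_in_band(pop$age_band[stratum])

    # True category per respondent from the per-sex distribution.
    pmat <- as.matrix(truth$prevalence[, consumption_levels()])
    rownames(pmat) <- truth$prevalence$sex
    u <- runif(n)
    cum <- t(apply(pmat, 1, cumsum))
    cat_idx <- rep(1L, n)
    for (s in rownames(cum)) {
      i <- sex == s
      cat_idx[i] <- findInterval(u[i], c(0, cum[s, ]), left.open = TRUE)
    }
    level <- consumption_levels()[pmin(cat_idx, 4L)]

    # Grams/day strictly interior to the category so the round trip through
    # unit counts can never cross a boundary.
    gpd <- numeric(n)
    gpd[level == "light"] <- runif(sum(level == "light"), 0.2, 12.4)
    gpd[level == "moderate"] <- runif(sum(level == "moderate"), 12.7, 49.5)
    gpd[level == "heavy"] <- runif(sum(level == "heavy"), 50.5, 120)

    freq_unit <- ifelse(gpd > 0 & gpd * DAYS_PER_WEEK / grams_per_unit < 1,
                        "month", "week")
    days <- ifelse(freq_unit == "week", DAYS_PER_WEEK, DAYS_PER_MONTH)
    total_units <- gpd * days / grams_per_unit
    shares <- matrix(stats::rexp(3 * n), ncol = 3)
    shares <- shares / rowSums(shares)
    units <- shares * total_units

    # Inverse-probability weights with lognormal noise, mean 1.
    n_stratum <- tabulate(stratum, nbins = nrow(pop))
    base_w <- pop$population[stratum] / pmax(n_stratum[stratum], 1)
    weight <- base_w * rlnorm(n, meanlog = -0.3^2 / 2, sdlog = 0.3)

    out <- tibble(
      respondent_id = sprintf("R%06d", seq_len(n)),
      sex = sex, age = age, weight = weight,
      beer_units = units[, 1], wine_units = units[, 2],
      spirits_units = units[, 3], freq_unit = freq_unit
    )
    # ground-truth assignment, for generator self-checks
    attr(out, "true_level") <- level
    out
  })
}

draw_age_in_band <- function(band) {
  lo <- c("18-29" = 18, "30-39" = 30, "40-49" = 40,
          "50-59" = 50, "60-69" = 60, "70+" = 70)[band]
  hi <- c("18-29" = 29, "30-39" = 39, "40-49" = 49,
          "50-59" = 59, "60-69" = 69, "70+" = 89)[band]
  unname(lo + floor(runif(length(band)) * (hi - lo + 1)))
}

FILLER_ICD10 <- c("I21", "I64", "J18", "J44", "E11", "K70", "A41",
                  "C34", "C16", "C67")

#' Generate a synthetic cause-of-death registry
#'
#' Death counts per site x sex x age band are Poisson draws around the
#' baseline non-drinker rate inflated by the population exposure mix
#' (\eqn{1 + \sum_i P_i (RR_i - 1)}), so the analytic PAF is, by
#' construction, the expected attributable fraction in the registry.
#' Records carry an ICD-10 code drawn from the site's code set; filler
#' records with non-target codes are mixed in at `truth$nontarget_rate`,
#' and a fraction `truth$missingness_rate` of all records has age and/or
#' sex blanked.
#'
#' @param truth A [ground_truth()].
#' @param year Calendar year label stamped on every record (default 2018).
#' @return Tibble with the registry CSV schema: `record_id`, `icd10`,
#'   `sex` (NA allowed), `age` (NA allowed), `year`.
#' @export
generate_registry <- function(truth, year = 2018) {
  validate_ground_truth(truth)
  sites_all <- cancer_sites(extended = TRUE)
  rr <- censor_nonsignificant(truth$rr)
  with_seed(truth$seed + 202L, {
    strata <- truth$baseline_death_rate |>
      inner_join(truth$population_counts, by = c("sex", "age_band"))
    infl <- vapply(seq_len(nrow(strata)), function(i) {
      p <- prevalence_vector(truth$prevalence, strata$sex[i])
      rrv <- vapply(exposed_levels(), function(lv) {
        hit <- rr$rr[rr$site == strata$site[i] & rr$sex == strata$sex[i] &
                       rr$level == lv]
        if (length(hit) == 0) 1 else hit
      }, numeric(1))
      1 + sum(p * (rrv - 1))
    }, numeric(1))
    deaths <- rpois(nrow(strata), strata$population * strata$rate * infl)

    recs <- strata[rep(seq_len(nrow(strata)), deaths), c("site", "sex", "age_band")]
    code_sets <- lapply(sites_all$icd10, expand_icd10_codes)
    names(code_sets) <- sites_all$site
    icd <- vapply(recs$site, function(s) {
      cs <- code_sets[[s]]
      cs[sample.int(length(cs), 1L)]
    }, character(1))
    target <- tibble(icd10 = unname(icd), sex = recs$sex,
                     age = draw_age_in_band(recs$age_band))

    n_target <- nrow(target)
    n_filler <- rpois(1, n_target * truth$nontarget_rate /
                        (1 - truth$nontarget_rate))
    pop <- truth$population_counts
    fs <- sample.int(nrow(pop), n_filler, replace = TRUE,
                     prob = pop$population / sum(pop$population))
    filler <- tibble(
      icd10 = FILLER_ICD10[sample.int(length(FILLER_ICD10), n_filler,
                                      replace = TRUE)],
      sex = pop$sex[fs], age = draw_age_in_band(pop$age_band[fs])
    )

    out <- bind_rows(target, filler)
    if (nrow(out) > 0) {
      out <- out[sample.int(nrow(out)), , drop = FALSE]
      blank <- runif(nrow(out)) < truth$missingness_rate
      which_field <- runif(nrow(out))
      out$age[blank & which_field < 0.55] <- NA
      out$sex[blank & which_field >= 0.45] <- NA
    }
    tibble(record_id = sprintf("D%07d", seq_len(nrow(out))),
           icd10 = out$icd10, sex = out$sex, age = out$age, year = year)
  })
}

#' Generate a stylized life table
#'
#' Residual life expectancy per age band, strictly decreasing with age,
#' shaped like the WHO estimates for a middle-income country: roughly 52
#' remaining years in the youngest adult band down to about 9.5 years at
#' 70+ under the default `max_age`.
#'
#' @param max_age Oldest age the table reaches (default 95, > 0).
#' @return Tibble `age_band`, `life_expectancy_years`.
#' @export
generate_life_table <- function(max_age = 95) {
  assert_that(is.numeric(max_age) && max_age > 0, "max_age must be positive")
  mid <- c(23.5, 34.5, 44.5, 54.5, 64.5, 77)
  assert_that(max_age > max(mid), "max_age must exceed the oldest band midpoint")
  taper <- seq(0.73, 0.53, length.out = length(mid))
  le <- (max_age - mid) * taper
  assert_that(all(diff(le) < 0), "life expectancy must decrease with age")
  tibble(age_band = age_bands(), life_expectancy_years = round(le, 1))
}

#' Generate synthetic YLD inputs
#'
#' For every site x sex x age band in the ground truth, builds the four
#' sequela prevalences (diagnosis/primary therapy, controlled, metastatic,
#' terminal) from the local death rate via stylized phase durations, and
#' attaches GBD-style cancer disability weights. Prevalences scale with
#' the death rate so morbidity tracks mortality, as it does for the
#' largely fatal cancers modelled here.
#'
#' @param truth A [ground_truth()].
#' @return Tibble with the YLD input CSV schema: `site`, `sex`,
#'   `age_band`, `prev_diagnosis`, `prev_controlled`, `prev_metastatic`,
#'   `prev_terminal`, `dw_diagnosis`, `dw_controlled`, `dw_metastatic`,
#'   `dw_terminal`, `population`.
#' @export
generate_yld_table <- function(truth) {
  validate_ground_truth(truth)
  with_seed(truth$seed + 303L, {
    rr <- censor_nonsignificant(truth$rr)
    base <- truth$baseline_death_rate |>
      inner_join(truth$population_counts, by = c("sex", "age_band"))
    infl <- vapply(seq_len(nrow(base)), function(i) {
      p <- prevalence_vector(truth$prevalence, base$sex[i])
      rrv <- vapply(exposed_levels(), function(lv) {
        hit <- rr$rr[rr$site == base$site[i] & rr$sex == base$sex[i] &
                       rr$level == lv]
        if (length(hit) == 0) 1 else hit
      }, numeric(1))
      1 + sum(p * (rrv - 1))
    }, numeric(1))
    inc <- base$rate * infl  # incidence proxy: mortality scale
    noise <- function() rlnorm(nrow(base), -0.1^2 / 2, 0.1)
    tibble(
      site = base$site, sex = base$sex, age_band = base$age_band,
      prev_diagnosis = pmin(inc * 0.5 * noise(), 0.99),
      prev_controlled = pmin(inc * 3.0 * noise(), 0.99),
      prev_metastatic = pmin(inc * 0.3 * noise(), 0.99),
      prev_terminal = pmin(inc * 0.1 * noise(), 0.99),
      dw_diagnosis = 0.288, dw_controlled = 0.049,
      dw_metastatic = 0.451, dw_terminal = 0.540,
      population = base$population
    )
  })
}

#' Cohort micro-simulation of deaths by exposure level
#'
#' Simulates `n` individuals allocated to the reference class and the
#' exposed levels by `prevalence`; each individual dies with probability
#' `baseline_risk * rr` of their level. Factual deaths are generated as
#' counterfactual (baseline-risk) deaths plus excess deaths through an
#' exact nested-binomial decomposition, which couples the factual and
#' counterfactual worlds through common randomness: the empirical excess
#' fraction \eqn{(D - D_{cf}) / D} is then a low-variance unbiased
#' estimator of the analytic attributable fraction, making the simulation
#' an independent oracle for [paf_total()].
#'
#' @param prevalence Exposed-level proportions (sum <= 1; remainder is the
#'   reference class).
#' @param rr Non-negative relative risks, one per exposed level.
#' @param baseline_risk Death probability in the reference class;
#'   `baseline_risk * max(rr)` must not exceed 1.
#' @param n Cohort size.
#' @param seed Integer seed.
#' @return Tibble with one row per level (reference first): `level`, `n`,
#'   `deaths`, `deaths_counterfactual`.
#' @export
simulate_cohort_deaths <- function(prevalence, rr, baseline_risk, n, seed) {
  assert_that(length(prevalence) == length(rr),
              "prevalence and rr must have equal length")
  assert_probability(prevalence, "exposed-level prevalences")
  assert_that(sum(prevalence) <= 1 + 1e-12,
              "exposed-level prevalences must sum to at most 1")
  assert_that(all(rr >= 0), "relative risks must be non-negative")
  assert_probability(baseline_risk, "baseline_risk")
  assert_that(baseline_risk * max(c(rr, 1)) <= 1,
              "baseline_risk * max(rr) must not exceed 1: not a probability")
  assert_that(is.numeric(n) && length(n) == 1 && n >= 1, "n must be positive")
  nm <- names(prevalence)
  if (is.null(nm)) {
    nm <- if (length(prevalence) == 3) exposed_levels()
          else paste0("level_", seq_along(prevalence))
  }
  with_seed(seed, {
    probs <- c(1 - sum(prevalence), prevalence)
    counts <- as.integer(rmultinom(1, as.integer(n), probs))
    b <- baseline_risk
    lv_rr <- c(1, rr)
    d_cf <- d_fact <- integer(length(counts))
    for (i in seq_along(counts)) {
      d_cf[i] <- rbinom(1, counts[i], b)
      r <- lv_rr[i]
      if (r >= 1) {
        # survivors of the counterfactual draw die with the excess hazard
        p_ex <- if (b < 1) b * (r - 1) / (1 - b) else 0
        d_fact[i] <- d_cf[i] + rbinom(1, counts[i] - d_cf[i], min(p_ex, 1))
      } else {
        # protective: factual deaths are a thinning of counterfactual ones
        d_fact[i] <- rbinom(1, d_cf[i], r)
      }
    }
    tibble(level = c("non_drinker", nm), n = counts,
           deaths = d_fact, deaths_counterfactual = d_cf)
  })
}

#' Empirical attributable fraction from a cohort simulation
#'
#' Computes \eqn{(D - D_{cf}) / D} from [simulate_cohort_deaths()] output,
#' with a delta-method standard error treating excess and counterfactual
#' deaths as independent Poisson-like counts.
#'
#' @param sim Output of [simulate_cohort_deaths()].
#' @return List with `estimate` and `se` (both `NA` if no deaths occurred,
#'   with a warning).
#' @export
empirical_paf <- function(sim) {
  assert_columns(sim, c("deaths", "deaths_counterfactual"), "simulation output")
  D <- sum(sim$deaths)
  C <- sum(sim$deaths_counterfactual)
  if (D == 0) {
    warning("no deaths simulated; attributable fraction undefined", call. = FALSE)
    return(list(estimate = NA_real_, se = NA_real_))
  }
  E <- D - C
  est <- E / D
  se <- sqrt(max((1 - est)^2 * abs(E) + est^2 * C, 0)) / D
  list(estimate = est, se = se)
}
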