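# Fixtures built in code: a small two-site world with known parameters,
# random valid PAF configurations, and a tiny registry.

fixture_rr <- function() {
  rr_table(tibble::tibble(
    site = rep(c("esophagus", "breast"), each = 3),
    sex = c(rep("M", 3), rep("F", 3)),
    level = rep(exposed_levels(), 2),
    rr = c(1.2, 2.0, 4.0, 1.1, 1.3, 1.6),
    significant = TRUE
  ))
}

fixture_prevalence <- function() {
  tibble::tibble(
    sex = c("M", "F"),
    non_drinker = c(0.2, 0.5),
    light = c(0.5, 0.3),
    moderate = c(0.2, 0.15),
    heavy = c(0.1, 0.05)
  )
}

fixture_truth <- function(seed = 7L, missingness_rate = 0.007,
                          nontarget_rate = 0.10) {
  pop <- tibble::tibble(
    sex = rep(c("M", "F"), each = 6),
    age_band = rep(age_bands(), 2),
    population = rep(c(30000, 25000, 20000, 15000, 10000, 8000), 2)
  )
  bdr <- tidyr::expand_grid(
    site = "esophagus", sex = "M", age_band = age_bands()
  ) |>
    dplyr::mutate(rate = c(0.0001, 0.0003, 0.001, 0.003, 0.008, 0.02)) |>
    dplyr::bind_rows(
      tidyr::expand_grid(site = "breast", sex = "F", age_band = age_bands()) |>
        dplyr::mutate(rate = c(0.0002, 0.0006, 0.002, 0.004, 0.006, 0.01))
    )
  ground_truth(fixture_prevalence(), fixture_rr(), bdr, pop,
               missingness_rate = missingness_rate,
               nontarget_rate = nontarget_rate, seed = seed)
}

# Random valid (p, rr) configuration for property-style tests.
random_paf_config <- function(max_rr = 6, monotone = FALSE) {
  p <- stats::runif(3)
  p <- p / sum(p) * stats::runif(1, 0.2, 0.95)  # leave a reference class
  rr <- 1 + stats::runif(3) * (max_rr - 1)
  if (monotone) rr <- sort(rr)
  list(p = p, rr = rr)
}

fixture_life_table <- function() {
  tibble::tibble(age_band = age_bands(),
                 life_expectancy_years = c(52, 43, 34, 26, 18, 9.5))
}
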