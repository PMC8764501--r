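# Burden module: registry filtering and grouping, attributable deaths,
# YLL, YLD, DALY assembly.

#' Filter a death registry and group deaths by site, sex and age band
#'
#' Applies the registry cleaning rules: records with a malformed ICD-10
#' code are skipped with a warning and counted; records missing sex and/or
#' age are excluded and counted; remaining records are mapped to cancer
#' sites through the configured ICD-10 code sets (three-character prefix
#' matching, ranges like C18-C20 expanded); codes outside every configured
#' site — and target codes for an inapplicable sex, such as breast cancer
#' in men under the default configuration — are ignored but tallied. The
#' counts always reconcile: `n_malformed + n_missing + n_ignored +
#' n_grouped = n_input`.
#'
#' @param records Registry data frame with columns `icd10`, `sex`, `age`.
#' @param sites Site configuration from [cancer_sites()].
#' @return List with `deaths` (tibble `site`, `sex`, `age_band`, `deaths`)
#'   and `exclusions` (one-row tibble of the reconciliation counts, with
#'   `n_ignored` split into `n_nontarget` and `n_inapplicable_sex`).
#' @export
filter_and_group <- function(records, sites = cancer_sites()) {
  assert_columns(records, c("icd10", "sex", "age"), "registry data")
  n_input <- nrow(records)

  malformed <- is.na(records$icd10) |
    !grepl("^[A-Za-z][0-9]{2}", as.character(records$icd10))
  if (any(malformed)) {
    warning(sprintf("skipping %d record(s) with malformed ICD-10 codes",
                    sum(malformed)), call. = FALSE)
  }
  rec <- records[!malformed, , drop = FALSE]

  missing_demo <- is.na(rec$sex) | is.na(rec$age)
  n_missing <- sum(missing_demo)
  rec <- rec[!missing_demo, , drop = FALSE]

  site <- icd10_to_site(rec$icd10, sites)
  nontarget <- is.na(site)
  sex_ok <- rep(TRUE, nrow(rec))
  sexes <- applicable_sexes(sites)
  names(sexes) <- sites$site
  hit <- which(!nontarget)
  if (length(hit) > 0) {
    sex_ok[hit] <- mapply(function(s, sx) sx %in% sexes[[s]],
                          site[hit], rec$sex[hit])
  }
  inapplicable <- !nontarget & !sex_ok
  keep <- !nontarget & sex_ok

  deaths <- tibble(site = site[keep], sex = rec$sex[keep],
                   age_band = age_to_band(rec$age[keep])) |>
    count(.data$site, .data$sex, .data$age_band, name = "deaths")

  exclusions <- tibble(
    n_input = n_input,
    n_malformed = sum(malformed),
    n_missing = n_missing,
    n_nontarget = sum(nontarget),
    n_inapplicable_sex = sum(inapplicable),
    n_ignored = sum(nontarget) + sum(inapplicable),
    n_grouped = sum(keep)
  )
  list(deaths = deaths, exclusions = exclusions)
}

#' Alcohol-attributable deaths
#'
#' Multiplies site/sex/age-band death counts by the site- and sex-specific
#' PAF: the same sex-level PAF applies to every age band. Attributable
#' counts are kept as reals; rounding happens only in the reporting layer.
#'
#' @param deaths Tibble `site`, `sex`, `age_band`, `deaths` from
#'   [filter_and_group()].
#' @param paf Tibble from [paf_table()].
#' @return `deaths` with added columns `deaths_attrib`,
#'   `deaths_attrib_light`, `deaths_attrib_moderate`, `deaths_attrib_heavy`.
#' @export
attributable_deaths <- function(deaths, paf) {
  assert_columns(deaths, c("site", "sex", "age_band", "deaths"), "death counts")
  joined <- left_join(deaths, paf, by = c("site", "sex"))
  no_paf <- is.na(joined$paf_total) & joined$deaths > 0
  assert_that(!any(no_paf), sprintf(
    "no PAF available for (site, sex) with deaths: %s",
    paste(unique(paste(joined$site[no_paf], joined$sex[no_paf], sep = "/")),
          collapse = ", ")))
  joined |>
    mutate(deaths_attrib = .data$deaths * .data$paf_total,
           deaths_attrib_light = .data$deaths * .data$paf_light,
           deaths_attrib_moderate = .data$deaths * .data$paf_moderate,
           deaths_attrib_heavy = .data$deaths * .data$paf_heavy) |>
    select(-starts_with("paf_"), -any_of("n_levels"))
}

#' Years of life lost
#'
#' YLL = deaths x residual life expectancy at the age band of death, read
#' directly at the band (no interpolation).
#'
#' @param deaths Tibble with `age_band` and `deaths` columns (any further
#'   stratification columns are carried through).
#' @param life_table Tibble `age_band`, `life_expectancy_years`.
#' @return `deaths` with an added `yll` column.
#' @export
compute_yll <- function(deaths, life_table) {
  assert_columns(deaths, c("age_band", "deaths"), "death counts")
  assert_columns(life_table, c("age_band", "life_expectancy_years"), "life table")
  assert_that(all(life_table$life_expectancy_years > 0),
              "life expectancies must be positive")
  missing_bands <- setdiff(unique(deaths$age_band), life_table$age_band)
  assert_that(length(missing_bands) == 0, sprintf(
    "no life-table entry for age band(s): %s",
    paste(missing_bands, collapse = ", ")))
  deaths |>
    inner_join(life_table, by = "age_band") |>
    mutate(yll = .data$deaths * .data$life_expectancy_years) |>
    select(-"life_expectancy_years")
}

#' Years lived with disability
#'
#' YLD = population x sum over the four cancer sequelae (diagnosis and
#' primary therapy, controlled, metastatic, terminal) of sequela
#' prevalence x disability weight.
#'
#' @param yld_inputs Tibble with the YLD input schema (see
#'   [generate_yld_table()]).
#' @return Tibble `site`, `sex`, `age_band`, `yld`.
#' @export
compute_yld <- function(yld_inputs) {
  prev_cols <- c("prev_diagnosis", "prev_controlled", "prev_metastatic",
                 "prev_terminal")
  dw_cols <- c("dw_diagnosis", "dw_controlled", "dw_metastatic", "dw_terminal")
  assert_columns(yld_inputs, c("site", "sex", "age_band", prev_cols, dw_cols,
                               "population"), "YLD inputs")
  assert_probability(unlist(yld_inputs[prev_cols]), "sequela prevalences")
  assert_probability(unlist(yld_inputs[dw_cols]), "disability weights",
                     open = TRUE)
  assert_that(all(yld_inputs$population >= 0),
              "population counts must be non-negative")
  pm <- as.matrix(yld_inputs[prev_cols])
  dm <- as.matrix(yld_inputs[dw_cols])
  tibble(site = yld_inputs$site, sex = yld_inputs$sex,
         age_band = yld_inputs$age_band,
         yld = yld_inputs$population * rowSums(pm * dm))
}

#' Assemble the full burden table
#'
#' Combines deaths, YLLs and YLDs per site x sex x age band, sums YLL and
#' YLD into DALYs, and applies the site/sex PAF (total and per level) to
#' every measure. Strata present in only one of the death and YLD inputs
#' are kept with the other measure at zero.
#'
#' @param deaths Tibble `site`, `sex`, `age_band`, `deaths`.
#' @param life_table Tibble `age_band`, `life_expectancy_years`.
#' @param yld_inputs YLD input tibble (see [compute_yld()]).
#' @param paf Tibble from [paf_table()].
#' @return Tibble, one row per site x sex x age band, with totals and
#'   attributable values (total and per consumption level) for deaths,
#'   YLL, YLD and DALY. `daly_* = yll_* + yld_*` exactly.
#' @export
assemble_burden <- function(deaths, life_table, yld_inputs, paf) {
  yll <- compute_yll(deaths, life_table) |>
    select("site", "sex", "age_band", "deaths", "yll")
  yld <- compute_yld(yld_inputs)
  strata <- full_join(yll, yld, by = c("site", "sex", "age_band")) |>
    mutate(deaths = dplyr::coalesce(.data$deaths, 0),
           yll = dplyr::coalesce(.data$yll, 0),
           yld = dplyr::coalesce(.data$yld, 0),
           daly = .data$yll + .data$yld)
  joined <- left_join(strata, paf, by = c("site", "sex"))
  nonzero <- joined$deaths + joined$daly > 0
  assert_that(!any(is.na(joined$paf_total) & nonzero),
              "missing PAF for a stratum with nonzero burden")
  joined <- joined |> filter(!is.na(.data$paf_total))
  out <- joined |>
    rename(deaths_total = "deaths", yll_total = "yll",
           yld_total = "yld", daly_total = "daly")
  for (m in c("deaths", "yll", "yld", "daly")) {
    tot <- out[[paste0(m, "_total")]]
    out[[paste0(m, "_attrib")]] <- tot * out$paf_total
    for (lv in exposed_levels()) {
      out[[paste0(m, "_attrib_", lv)]] <- tot * out[[paste0("paf_", lv)]]
    }
  }
  out |> select(-starts_with("paf_"), -any_of("n_levels"))
}

#' Aggregate a burden table over strata
#'
#' Sums every measure over the dropped stratification columns.
#'
#' @param burden Output of [assemble_burden()].
#' @param by Columns to keep, e.g. `c("site", "sex")` (default) or `"sex"`.
#' @return Aggregated tibble.
#' @export
aggregate_burden <- function(burden, by = c("site", "sex")) {
  burden |>
    group_by(across(all_of(by))) |>
    summarise(across(where(is.numeric), sum), .groups = "drop")
}
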