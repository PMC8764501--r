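# Reporting: publication-style tables, level-share summaries, pipeline
# orchestration, and the published reference figures used for calibration
# checks.

#' Render a publication-style attributable-burden table
#'
#' One row per site plus an "All selected cancer types" row; for each sex
#' and consumption level (all, light, moderate, heavy) the attributable N
#' (rounded to integer) and the PAF as a whole percent. The PAF
#' denominator is the total of the measure for that site and sex (for the
#' all-sites row, the total across sites per sex). Sites not applicable to
#' a sex (breast in men) appear with NA in that sex's columns. Rounding
#' happens here and only here; totals are computed before rounding, so a
#' rendered total may differ by one unit from the sum of rendered rows.
#'
#' @param burden Output of [assemble_burden()].
#' @param measure `"deaths"` or `"dalys"`.
#' @param sites Site configuration (used for labels and row order).
#' @return Long tibble: `site_label`, `sex`, `level`
#'   (`all`/`light`/`moderate`/`heavy`), `n` (rounded), `paf_pct`
#'   (whole percent).
#' @export
render_burden_table <- function(burden, measure = c("deaths", "dalys"),
                                sites = cancer_sites()) {
  measure <- match.arg(measure)
  stem <- if (measure == "deaths") "deaths" else "daly"
  agg <- aggregate_burden(burden, by = c("site", "sex"))
  all_row <- aggregate_burden(burden, by = "sex") |> mutate(site = ".all")
  agg <- bind_rows(agg, all_row)
  labels <- c(setNames(sites$label, sites$site),
              ".all" = "All selected cancer types")
  lv_cols <- c(all = paste0(stem, "_attrib"),
               setNames(paste0(stem, "_attrib_", exposed_levels()),
                        exposed_levels()))
  total_col <- paste0(stem, "_total")
  out <- lapply(names(lv_cols), function(lv) {
    tibble(site = agg$site, sex = agg$sex, level = lv,
           n_raw = agg[[lv_cols[[lv]]]],
           total_raw = agg[[total_col]])
  })
  bind_rows(out) |>
    mutate(site_label = labels[.data$site],
           n = round(.data$n_raw),
           paf_pct = ifelse(.data$total_raw > 0,
                            round(.data$n_raw / .data$total_raw * 100), 0),
           level = factor(.data$level,
                          levels = c("all", exposed_levels()))) |>
    arrange(match(.data$site, names(labels)), .data$sex, .data$level) |>
    select("site", "site_label", "sex", "level", "n", "paf_pct",
           "n_raw", "total_raw")
}

#' Shares of attributable burden by consumption level
#'
#' For each sex (and pooled across sexes, `sex = "all"`), the share of the
#' attributable burden contributed by each exposed level:
#' attributable(level) / attributable(all levels). Shares sum to 1. A
#' stratum with zero attributable burden gets NA shares with a warning.
#'
#' @param burden Output of [assemble_burden()].
#' @param measure `"deaths"` or `"dalys"`.
#' @return Tibble `sex`, `level`, `attrib`, `share`.
#' @export
level_share_summary <- function(burden, measure = c("deaths", "dalys")) {
  measure <- match.arg(measure)
  stem <- if (measure == "deaths") "deaths" else "daly"
  cols <- paste0(stem, "_attrib_", exposed_levels())
  per_sex <- burden |>
    group_by(.data$sex) |>
    summarise(across(all_of(cols), sum), .groups = "drop")
  pooled <- burden |>
    summarise(across(all_of(cols), sum)) |>
    mutate(sex = "all")
  long <- bind_rows(per_sex, pooled) |>
    pivot_longer(all_of(cols), names_to = "level", values_to = "attrib") |>
    mutate(level = sub(paste0(stem, "_attrib_"), "", .data$level, fixed = TRUE)) |>
    group_by(.data$sex) |>
    mutate(total = sum(.data$attrib),
           share = ifelse(.data$total > 0, .data$attrib / .data$total,
                          NA_real_)) |>
    ungroup()
  if (any(long$total == 0)) {
    warning("zero attributable burden in at least one stratum; shares undefined",
            call. = FALSE)
  }
  long |> select("sex", "level", "attrib", "share")
}

#' Run the full synthetic pipeline end to end
#'
#' Generates all five inputs from a ground truth, estimates prevalence,
#' computes PAFs, assembles the burden table, renders the deaths and DALYs
#' reports and level shares, and evaluates the scenario presets. When
#' `out_dir` is given, writes every table as CSV plus a plain-text run log
#' stamped with the seed and a configuration hash. Deterministic given the
#' seed.
#'
#' @param seed Integer seed.
#' @param n_respondents Survey size (default 29224, the size of the
#'   national survey round being emulated).
#' @param truth Optional [ground_truth()]; default
#'   `default_ground_truth(seed, extended)`.
#' @param extended Include sensitivity-analysis sites (default FALSE).
#' @param scenarios Named list of [scenario_spec()]s (default
#'   [scenario_presets()]).
#' @param out_dir Optional output directory.
#' @return Invisibly, a list with every intermediate and final table.
#' @export
run_pipeline <- function(seed = 1L, n_respondents = 29224, truth = NULL,
                         extended = FALSE, scenarios = scenario_presets(),
                         out_dir = NULL) {
  truth <- truth %||% default_ground_truth(seed = seed, extended = extended)
  sites <- cancer_sites(extended = extended)
  log_lines <- c(sprintf("seed: %d", as.integer(seed)),
                 sprintf("n_respondents: %d", as.integer(n_respondents)),
                 sprintf("extended_sites: %s", extended))

  stage <- function(name, code) {
    tryCatch(force(code), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  survey <- stage("synthetic_data", generate_survey(truth, n_respondents))
  registry <- stage("synthetic_data", generate_registry(truth))
  life_table <- stage("synthetic_data", generate_life_table())
  yld_inputs <- stage("synthetic_data", generate_yld_table(truth))
  log_lines <- c(log_lines,
                 sprintf("survey records: %d", nrow(survey)),
                 sprintf("registry records: %d", nrow(registry)))

  prevalence <- stage("exposure", weighted_prevalence(survey, by = "sex"))
  prevalence_by_age <- stage("exposure",
                             weighted_prevalence(survey, by = c("sex", "age_band")))
  rr <- stage("risk_inputs", censor_nonsignificant(truth$rr))
  paf <- stage("paf_engine", paf_table(prevalence, rr, sites))
  grouped <- stage("burden", filter_and_group(registry, sites))
  log_lines <- c(log_lines, sprintf(
    "registry: %d grouped, %d missing sex/age, %d non-target, %d malformed",
    grouped$exclusions$n_grouped, grouped$exclusions$n_missing,
    grouped$exclusions$n_ignored, grouped$exclusions$n_malformed))
  burden <- stage("burden",
                  assemble_burden(grouped$deaths, life_table, yld_inputs, paf))

  table_deaths <- stage("reporting", render_burden_table(burden, "deaths", sites))
  table_dalys <- stage("reporting", render_burden_table(burden, "dalys", sites))
  shares_deaths <- stage("reporting", level_share_summary(burden, "deaths"))
  shares_dalys <- stage("reporting", level_share_summary(burden, "dalys"))

  scenario_inputs <- list(prevalence = prevalence, rr = rr, sites = sites,
                          deaths = grouped$deaths, life_table = life_table,
                          yld_inputs = yld_inputs)
  scenario_results <- stage("scenarios", bind_rows(
    lapply(scenarios, function(sp) evaluate_scenario(scenario_inputs, sp))))
  log_lines <- c(log_lines,
                 sprintf("attributable deaths: %.1f", sum(burden$deaths_attrib)),
                 sprintf("attributable DALYs: %.1f", sum(burden$daly_attrib)))

  result <- list(truth = truth, survey = survey, registry = registry,
                 life_table = life_table, yld_inputs = yld_inputs,
                 prevalence = prevalence, prevalence_by_age = prevalence_by_age,
                 rr = rr, paf = paf, deaths = grouped$deaths,
                 exclusions = grouped$exclusions, burden = burden,
                 table_deaths = table_deaths, table_dalys = table_dalys,
                 shares_deaths = shares_deaths, shares_dalys = shares_dalys,
                 scenarios = scenario_results)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    config_hash <- rlang::hash(list(seed, n_respondents, extended,
                                    truth$prevalence, truth$missingness_rate))
    write_one <- function(x, name) {
      write.csv(x, file.path(out_dir, paste0(name, ".csv")), row.names = FALSE)
    }
    write_one(survey, "survey")
    write_one(registry, "registry")
    write_one(life_table, "life_table")
    write_one(yld_inputs, "yld_inputs")
    write_one(prevalence, "prevalence")
    write_one(prevalence_by_age, "prevalence_by_age")
    write_one(paf, "paf")
    write_one(burden, "burden")
    write_one(table_deaths, "table_deaths")
    write_one(table_dalys, "table_dalys")
    write_one(shares_deaths, "level_shares_deaths")
    write_one(shares_dalys, "level_shares_dalys")
    write_one(scenario_results, "scenarios")
    writeLines(c(sprintf("config_hash: %s", config_hash), log_lines),
               file.path(out_dir, "run_log.txt"))
  }
  invisible(result)
}

#' Published national estimates used for calibration checks
#'
#' The published 2018 Argentine estimates of alcohol-attributable cancer
#' burden — per-site, per-sex, per-level attributable deaths and DALYs
#' with their attributable fractions, plus the headline totals and
#' scenario results — shipped as a plain-text table. These are reference
#' inputs for arithmetic-consistency checks and calibration, not outputs
#' of this package.
#'
#' @return List with `cells` (tibble: `measure`, `site`, `sex`, `level`,
#'   `n`, `paf_pct`) and `summary` (tibble: `quantity`, `value`).
#' @export
published_estimates <- function() {
  path <- system.file("extdata", "argentina_2018_published.csv",
                      package = "alcoburden")
  raw <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  list(
    cells = raw |> filter(.data$block == "cell") |>
      select("measure", "site", "sex", "level", "n", "paf_pct"),
    summary = raw |> filter(.data$block == "summary") |>
      select(quantity = "site", value = "n")
  )
}
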