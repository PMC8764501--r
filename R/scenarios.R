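# Counterfactual consumption-shift scenarios.

#' Define a consumption-shift scenario
#'
#' A scenario moves the entire population mass of one or more source
#' categories into lower categories, simultaneously, relative to the
#' baseline distribution. Only reductions are modelled: the destination
#' must rank strictly below the source in the consumption-level ordering.
#'
#' @param name Scenario label.
#' @param shifts Named character vector mapping source levels to
#'   destination levels, e.g. `c(heavy = "moderate")`. An empty vector is
#'   the identity scenario.
#' @return List of class `scenario_spec`.
#' @examples
#' scenario_spec("moderate to light", c(moderate = "light"))
#' @export
scenario_spec <- function(name, shifts = character()) {
  lv <- consumption_levels()
  assert_that(is.character(name) && length(name) == 1, "name must be a string")
  if (length(shifts) > 0) {
    assert_that(!is.null(names(shifts)) && all(names(shifts) %in% lv),
                "shift sources must be consumption levels")
    assert_that(all(shifts %in% lv), "shift destinations must be consumption levels")
    assert_that(!any(duplicated(names(shifts))), "duplicate shift sources")
    src_rank <- match(names(shifts), lv)
    dst_rank <- match(shifts, lv)
    assert_that(all(dst_rank < src_rank),
                "shifts must move mass to a strictly lower category")
  }
  structure(list(name = name, shifts = shifts), class = "scenario_spec")
}

#' Built-in scenarios
#'
#' The three published counterfactuals — heavy drinkers become moderate;
#' moderate drinkers become light; both shifts combined — plus full
#' abstention (all drinkers become non-drinkers), which by the definition
#' of the PAF prevents the whole attributable burden.
#'
#' @return Named list of [scenario_spec()] objects.
#' @export
scenario_presets <- function() {
  list(
    heavy_to_moderate = scenario_spec("heavy to moderate",
                                      c(heavy = "moderate")),
    moderate_to_light = scenario_spec("moderate to light",
                                      c(moderate = "light")),
    combined = scenario_spec("combined",
                             c(moderate = "light", heavy = "moderate")),
    full_abstention = scenario_spec("full abstention",
                                    c(light = "non_drinker",
                                      moderate = "non_drinker",
                                      heavy = "non_drinker"))
  )
}

#' Apply a scenario to a prevalence table
#'
#' All shifts are applied simultaneously from the baseline: each source
#' category's baseline mass is added to its destination and removed from
#' the source. Under the combined preset, the moderate class therefore
#' ends up holding exactly the baseline heavy mass. Proportions still sum
#' to 1 per stratum.
#'
#' @param prevalence Prevalence table from [weighted_prevalence()] (or the
#'   ground-truth prevalence tibble).
#' @param spec A [scenario_spec()].
#' @return The shifted prevalence table.
#' @export
apply_scenario <- function(prevalence, spec) {
  assert_that(inherits(spec, "scenario_spec"), "spec must be a scenario_spec")
  assert_columns(prevalence, consumption_levels(), "prevalence table")
  out <- prevalence
  baseline <- prevalence[consumption_levels()]
  for (src in names(spec$shifts)) {
    dst <- spec$shifts[[src]]
    out[[dst]] <- out[[dst]] + baseline[[src]]
    out[[src]] <- out[[src]] - baseline[[src]]
  }
  out
}

#' Evaluate a counterfactual scenario end to end
#'
#' Recomputes PAFs and attributable burden under the shifted prevalence
#' and reports the prevented deaths and DALYs, absolutely and as a
#' percentage of the baseline attributable burden. Observed total deaths
#' and DALYs are held fixed; only the attributable fraction changes.
#'
#' @param inputs List with elements `prevalence` (sex-stratified), `rr`
#'   (an [rr_table()]), `sites` (from [cancer_sites()]), `deaths`
#'   (site/sex/age-band counts from [filter_and_group()]), `life_table`
#'   and `yld_inputs`.
#' @param spec A [scenario_spec()].
#' @return One-row tibble: `scenario`, baseline and scenario attributable
#'   deaths/DALYs, `prevented_deaths`, `prevented_dalys`,
#'   `pct_deaths_prevented`, `pct_dalys_prevented`.
#' @export
evaluate_scenario <- function(inputs, spec) {
  needed <- c("prevalence", "rr", "sites", "deaths", "life_table", "yld_inputs")
  assert_that(is.list(inputs) && all(needed %in% names(inputs)),
              sprintf("inputs must contain: %s", paste(needed, collapse = ", ")))
  burden_for <- function(prev) {
    paf <- paf_table(prev, inputs$rr, inputs$sites)
    assemble_burden(inputs$deaths, inputs$life_table, inputs$yld_inputs, paf)
  }
  base <- burden_for(inputs$prevalence)
  scen <- burden_for(apply_scenario(inputs$prevalence, spec))
  b_deaths <- sum(base$deaths_attrib)
  b_dalys <- sum(base$daly_attrib)
  s_deaths <- sum(scen$deaths_attrib)
  s_dalys <- sum(scen$daly_attrib)
  tibble(
    scenario = spec$name,
    baseline_attrib_deaths = b_deaths,
    scenario_attrib_deaths = s_deaths,
    prevented_deaths = b_deaths - s_deaths,
    pct_deaths_prevented = if (b_deaths > 0) (b_deaths - s_deaths) / b_deaths * 100 else NA_real_,
    baseline_attrib_dalys = b_dalys,
    scenario_attrib_dalys = s_dalys,
    prevented_dalys = b_dalys - s_dalys,
    pct_dalys_prevented = if (b_dalys > 0) (b_dalys - s_dalys) / b_dalys * 100 else NA_real_
  )
}
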