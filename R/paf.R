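# PAF engine: multi-level population attributable fractions.

validate_paf_inputs <- function(p, rr) {
  assert_that(length(p) == length(rr),
              "prevalence and RR vectors must have equal length")
  assert_that(is.numeric(p) && !anyNA(p) && all(p >= 0 & p <= 1),
              "exposed-level prevalences must lie in [0, 1]")
  assert_that(sum(p) <= 1 + 1e-12,
              "exposed-level prevalences must sum to at most 1")
  assert_that(is.numeric(rr) && !anyNA(rr) && all(rr > 0),
              "relative risks must be positive")
  invisible(TRUE)
}

#' Population attributable fraction over multiple exposure levels
#'
#' Computes the attributable fraction
#' \deqn{PAF = \frac{\sum_i P_i (RR_i - 1)}{\sum_i P_i (RR_i - 1) + 1}}
#' where \eqn{P_i} is the population proportion at exposed level \eqn{i}
#' and \eqn{RR_i} the relative risk at that level relative to the
#' unexposed reference (the remainder of the population). This is the
#' proportional reduction in deaths or disease that would occur if
#' exposure were reduced to zero.
#'
#' @param p Numeric vector of exposed-level proportions (the reference
#'   class is the remainder to 1).
#' @param rr Positive relative risks, same length and order as `p`.
#'   Values below 1 (protective) are permitted and contribute negatively.
#' @return A single number, always below 1; non-negative whenever all
#'   `rr >= 1`.
#' @examples
#' paf_total(c(0.5, 0.2, 0.1), c(1.2, 2.0, 4.0))  # 0.6 / 1.6 = 0.375
#' @export
paf_total <- function(p, rr) {
  validate_paf_inputs(p, rr)
  excess <- sum(p * (rr - 1))
  denom <- excess + 1
  assert_that(denom > 0, "PAF denominator must be positive")
  excess / denom
}

#' Level-wise decomposition of the attributable fraction
#'
#' Splits the total PAF into per-level shares using the shared denominator:
#' \eqn{PAF_i = P_i (RR_i - 1) / (\sum_j P_j (RR_j - 1) + 1)}. This is the
#' only decomposition whose level terms sum exactly to the total PAF, which
#' is what makes per-level attributable counts additive.
#'
#' @inheritParams paf_total
#' @return Named numeric vector (names from `names(p)`, else
#'   [exposed_levels()] when length 3) summing exactly to [paf_total()].
#' @examples
#' paf_by_level(c(0.5, 0.2, 0.1), c(1.2, 2.0, 4.0))
#' @export
paf_by_level <- function(p, rr) {
  validate_paf_inputs(p, rr)
  denom <- sum(p * (rr - 1)) + 1
  assert_that(denom > 0, "PAF denominator must be positive")
  out <- p * (rr - 1) / denom
  nm <- names(p)
  if (is.null(nm) && length(p) == length(exposed_levels())) nm <- exposed_levels()
  setNames(as.numeric(out), nm)
}

#' PAF table over cancer sites and sexes
#'
#' Applies [paf_total()] and [paf_by_level()] to every applicable
#' (site, sex) pair: sex-level prevalences are combined with the censored
#' site- and sex-specific RRs. PAFs are computed per sex only — the RRs are
#' sex-specific and the exposure distribution used for attribution is the
#' sex-level one; age enters the pipeline later, through age-specific
#' deaths and life expectancy.
#'
#' @param prevalence Sex-stratified prevalence table from
#'   [weighted_prevalence()].
#' @param rr An [rr_table()] (censoring is applied internally).
#' @param sites Site configuration from [cancer_sites()].
#' @return Tibble with one row per applicable (site, sex):
#'   `paf_light`, `paf_moderate`, `paf_heavy`, `paf_total`, `n_levels`.
#'   Inapplicable pairs (breast in men by default) are absent.
#' @export
paf_table <- function(prevalence, rr, sites = cancer_sites()) {
  rr <- censor_nonsignificant(rr)
  sexes_by_site <- applicable_sexes(sites)
  rows <- list()
  for (i in seq_len(nrow(sites))) {
    for (sex in sexes_by_site[[i]]) {
      site <- sites$site[i]
      p <- prevalence_vector(prevalence, sex)
      rrv <- vapply(exposed_levels(), function(lv) {
        hit <- rr$rr[rr$site == site & rr$sex == sex & rr$level == lv]
        if (length(hit) == 0) 1 else hit
      }, numeric(1))
      by_level <- paf_by_level(p, rrv)
      rows[[length(rows) + 1L]] <- tibble(
        site = site, sex = sex,
        paf_light = by_level[["light"]],
        paf_moderate = by_level[["moderate"]],
        paf_heavy = by_level[["heavy"]],
        paf_total = paf_total(p, rrv),
        n_levels = length(exposed_levels())
      )
    }
  }
  bind_rows(rows)
}
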