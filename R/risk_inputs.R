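# Risk inputs: relative-risk table by cancer site x sex x consumption level,
# non-significance censoring, and the ICD-10 cancer-site configuration.

#' Construct and validate a relative-risk table
#'
#' One row per (site, sex, exposed level). The non-drinker reference level
#' has RR 1 by definition and is never stored.
#'
#' @param df Data frame with columns `site`, `sex` (`"M"`/`"F"`), `level`
#'   (one of [exposed_levels()]), `rr` (positive real) and `significant`
#'   (logical).
#' @return A validated tibble of class `rr_table`.
#' @export
rr_table <- function(df) {
  assert_columns(df, c("site", "sex", "level", "rr", "significant"), "RR table")
  assert_that(all(df$level %in% exposed_levels()),
              "RR table levels must be exposed levels (light/moderate/heavy)")
  assert_that(all(df$sex %in% sex_codes()), "RR table sex must be 'M' or 'F'")
  assert_that(is.numeric(df$rr) && !anyNA(df$rr) && all(df$rr > 0),
              "relative risks must be positive")
  assert_that(is.logical(df$significant) && !anyNA(df$significant),
              "significance flags must be TRUE/FALSE")
  assert_that(!any(duplicated(df[c("site", "sex", "level")])),
              "duplicate (site, sex, level) entries in RR table")
  out <- as_tibble(df)
  class(out) <- c("rr_table", class(out))
  out
}

#' Censor non-significant relative risks to 1
#'
#' Associations that were not statistically significant in the source
#' meta-analysis are assumed to carry no effect: their RR is replaced by
#' exactly 1. Significant entries pass through unchanged.
#'
#' @param rr An [rr_table()].
#' @return The table with `rr = 1` wherever `significant` is `FALSE`.
#' @export
censor_nonsignificant <- function(rr) {
  rr <- rr_table(rr)
  rr$rr[!rr$significant] <- 1
  rr
}

#' Look up a (censored) relative risk
#'
#' Returns the censored RR for a (site, sex, level) triple. The
#' non-drinker level always returns 1 (reference category). A missing
#' table entry returns 1 with a warning, mirroring the treatment of absent
#' associations as null. Looking up a site for a sex it does not apply to
#' (e.g. breast cancer in men under the default configuration) is a
#' configuration error.
#'
#' @param rr An [rr_table()].
#' @param site Cancer-site label.
#' @param sex `"M"` or `"F"`.
#' @param level One of [consumption_levels()].
#' @param sites Site configuration, default [cancer_sites()] with the
#'   extended set so sensitivity-analysis sites can be looked up too.
#' @return A single positive RR.
#' @export
lookup_rr <- function(rr, site, sex, level, sites = cancer_sites(extended = TRUE)) {
  assert_that(level %in% consumption_levels(), "unknown consumption level")
  cfg <- sites[sites$site == site, , drop = FALSE]
  assert_that(nrow(cfg) == 1, sprintf("unknown cancer site '%s'", site))
  if (!sex %in% strsplit(cfg$sexes, ",", fixed = TRUE)[[1]]) {
    stop(sprintf("site '%s' is not applicable to sex '%s'", site, sex),
         call. = FALSE)
  }
  if (level == "non_drinker") return(1)
  rr <- censor_nonsignificant(rr)
  hit <- rr$rr[rr$site == site & rr$sex == sex & rr$level == level]
  if (length(hit) == 0) {
    warning(sprintf("no RR entry for (%s, %s, %s); assuming RR = 1",
                    site, sex, level), call. = FALSE)
    return(1)
  }
  hit
}

#' Cancer-site configuration with ICD-10 code sets
#'
#' The six core sites with causal evidence for alcohol — oral cavity and
#' pharynx (C00-C14), esophagus (C15), colorectal (C18-C20), liver (C22),
#' larynx (C32) and female breast (C50) — plus, when `extended = TRUE`,
#' the three sensitivity-analysis sites melanoma (C43), pancreas (C25) and
#' prostate (C61).
#'
#' @param extended Include the sensitivity-analysis sites (default FALSE).
#' @param config Optional parsed RR/site configuration from
#'   [read_rr_config()]; defaults to the configuration shipped with the
#'   package.
#' @return Tibble with columns `site`, `label`, `icd10` (comma-separated
#'   codes/ranges), `sexes` (comma-separated applicable sexes) and
#'   `in_core_set`.
#' @export
cancer_sites <- function(extended = FALSE, config = NULL) {
  config <- config %||% default_rr_config()
  sites <- config$sites
  if (!extended) sites <- sites[sites$in_core_set, , drop = FALSE]
  codes <- lapply(sites$icd10, expand_icd10_codes)
  all_codes <- unlist(codes)
  assert_that(!any(duplicated(all_codes)),
              "ICD-10 code sets must be disjoint across sites")
  sites
}

# Expand "C00-C14,C18" into c("C00", ..., "C14", "C18").
expand_icd10_codes <- function(spec) {
  parts <- trimws(strsplit(spec, ",", fixed = TRUE)[[1]])
  out <- lapply(parts, function(p) {
    if (grepl("-", p, fixed = TRUE)) {
      ends <- strsplit(p, "-", fixed = TRUE)[[1]]
      assert_that(length(ends) == 2 && substr(ends[1], 1, 1) == substr(ends[2], 1, 1),
                  sprintf("malformed ICD-10 range '%s'", p))
      letter <- substr(ends[1], 1, 1)
      lo <- as.integer(substr(ends[1], 2, nchar(ends[1])))
      hi <- as.integer(substr(ends[2], 2, nchar(ends[2])))
      assert_that(!is.na(lo) && !is.na(hi) && lo <= hi,
                  sprintf("malformed ICD-10 range '%s'", p))
      sprintf("%s%02d", letter, lo:hi)
    } else {
      p
    }
  })
  unlist(out)
}

#' Map ICD-10 codes to cancer sites
#'
#' Matching is on the three-character category (letter + two digits), so
#' subcategory codes like "C15.3" or "C159" map to the same site as "C15".
#'
#' @param codes Character vector of ICD-10 codes.
#' @param sites Site configuration from [cancer_sites()].
#' @return Character vector of site labels; `NA` for codes outside every
#'   configured site.
#' @export
icd10_to_site <- function(codes, sites = cancer_sites()) {
  lut <- unlist(lapply(seq_len(nrow(sites)), function(i) {
    setNames(rep(sites$site[i], length(expand_icd10_codes(sites$icd10[i]))),
             expand_icd10_codes(sites$icd10[i]))
  }))
  key <- toupper(substr(gsub(".", "", codes, fixed = TRUE), 1, 3))
  unname(lut[key])
}

applicable_sexes <- function(sites) {
  lapply(strsplit(sites$sexes, ",", fixed = TRUE), trimws)
}

#' Read a relative-risk / site configuration file
#'
#' The configuration is a YAML document with two blocks: `sites` (site
#' label, ICD-10 codes, applicable sexes, core-set flag) and
#' `relative_risks` (one record per site x sex x exposed level with fields
#' `rr` and `significant`).
#'
#' @param path Path to the YAML file.
#' @return List with elements `sites` (tibble) and `rr` (an [rr_table()]).
#' @export
read_rr_config <- function(path) {
  assert_that(file.exists(path), sprintf("RR config file '%s' not found", path))
  raw <- yaml::read_yaml(path)
  assert_that(!is.null(raw$sites) && !is.null(raw$relative_risks),
              "RR config must contain 'sites' and 'relative_risks' blocks")
  sites <- bind_rows(lapply(raw$sites, as_tibble))
  sites$in_core_set <- as.logical(sites$in_core_set)
  rr <- rr_table(bind_rows(lapply(raw$relative_risks, as_tibble)))
  assert_that(all(rr$site %in% sites$site),
              "every RR entry must reference a configured site")
  list(sites = as_tibble(sites), rr = rr)
}

default_config_env <- new.env(parent = emptyenv())

#' Default (synthetic) relative-risk configuration
#'
#' The package ships a synthetic RR table (`inst/extdata/rr_synthetic.yaml`)
#' whose values are back-calculated from the published Argentine 2018
#' sex-level consumption prevalences and per-level attributable fractions,
#' so that the default pipeline reproduces the published attributable-
#' fraction structure. The underlying meta-analytic estimates themselves
#' are not redistributed; treat these values as calibration stand-ins, and
#' supply your own configuration for substantive work.
#'
#' @return List with elements `sites` and `rr` (see [read_rr_config()]).
#' @export
default_rr_config <- function() {
  if (is.null(default_config_env$config)) {
    path <- system.file("extdata", "rr_synthetic.yaml", package = "alcoburden")
    default_config_env$config <- read_rr_config(path)
  }
  default_config_env$config
}

#' Default synthetic relative-risk table
#'
#' @return The [rr_table()] from [default_rr_config()].
#' @export
default_rr_table <- function() {
  default_rr_config()$rr
}
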