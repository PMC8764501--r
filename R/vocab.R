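# Shared vocabulary: consumption levels, sexes, age bands, small helpers.

#' Alcohol consumption levels
#'
#' The four consumption categories used throughout the pipeline, in
#' increasing order of exposure: non-drinker (0 g ethanol/day), light
#' (0.1-12.5 g/day), moderate (12.6-50 g/day) and heavy (> 50 g/day).
#' Non-drinkers (including former drinkers) are the reference category of
#' the relative-risk table.
#'
#' @return Character vector of the four level names, ordered from
#'   non-drinker to heavy.
#' @export
consumption_levels <- function() {
  c("non_drinker", "light", "moderate", "heavy")
}

#' Exposed consumption levels
#'
#' The three non-reference levels that enter the attributable-fraction
#' formula.
#'
#' @return Character vector `c("light", "moderate", "heavy")`.
#' @export
exposed_levels <- function() {
  c("light", "moderate", "heavy")
}

#' Age bands used for stratification
#'
#' Six adult age bands: 18-29, 30-39, 40-49, 50-59, 60-69 and 70+.
#'
#' @return Character vector of band labels.
#' @export
age_bands <- function() {
  c("18-29", "30-39", "40-49", "50-59", "60-69", "70+")
}

sex_codes <- function() c("M", "F")

#' Map an age in years to its age band
#'
#' Ages below 30 map to "18-29" (the surveys and registries modelled here
#' cover adults; the occasional under-18 death record in a user-supplied
#' registry is folded into the youngest band rather than dropped).
#'
#' @param age Integer vector of ages in years; `NA` allowed.
#' @return Character vector of band labels (`NA` where `age` is `NA`).
#' @export
age_to_band <- function(age) {
  breaks <- c(-Inf, 29, 39, 49, 59, 69, Inf)
  as.character(cut(age, breaks = breaks, labels = age_bands()))
}

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Validation helpers --------------------------------------------------------

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  assert_that(
    length(missing) == 0,
    sprintf("%s is missing column(s): %s", what, paste(missing, collapse = ", "))
  )
}

assert_probability <- function(x, what, open = FALSE) {
  ok <- if (open) all(x > 0 & x < 1) else all(x >= 0 & x <= 1)
  assert_that(!anyNA(x) && ok,
              sprintf("%s must lie in %s", what, if (open) "(0, 1)" else "[0, 1]"))
}
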