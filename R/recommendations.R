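# Recommended fruit-and-vegetable consumption levels: the flat 400 g
# minimum and the WHO age-specific levels weighted by each country's
# population pyramid.

.fv_age_bands <- c("age_0_4", "age_5_14", "age_15plus")

#' WHO age-specific recommendation set
#'
#' 330 g/person/day for ages 0-4, 480 g for ages 5-14, 600 g for ages 15
#' and over.
#'
#' @return Named numeric vector over the three age bands.
#' @export
default_recommendations <- function() {
  c(age_0_4 = 330, age_5_14 = 480, age_15plus = 600)
}

#' Population-pyramid-weighted recommendation
#'
#' The average per-capita consumption level consistent with age-specific
#' recommendations and a given pyramid:
#' \deqn{R = \sum_a N_a r_a / \sum_a N_a}
#' where \eqn{N_a} is the population in age band \eqn{a} and \eqn{r_a} the
#' band's recommended level. R is invariant under uniform rescaling of the
#' pyramid and always lies between the smallest and largest band level.
#'
#' @param pyramid Named numeric vector of band populations; names must
#'   cover `age_0_4`, `age_5_14`, `age_15plus`. All entries must be
#'   non-negative with a positive sum.
#' @param recs Named recommendation levels (g/person/day), one per band;
#'   defaults to [default_recommendations()].
#' @return Weighted recommendation in g/person/day.
#' @export
#' @examples
#' age_weighted_target(c(age_0_4 = 1e6, age_5_14 = 2e6, age_15plus = 7e6))
age_weighted_target <- function(pyramid, recs = default_recommendations()) {
  bands <- names(recs)
  if (is.null(bands) || any(!nzchar(bands))) {
    stop("schema error: recommendations must be a named vector")
  }
  if (any(recs <= 0)) stop("recommendation levels must be strictly positive")
  missing <- setdiff(bands, names(pyramid))
  if (length(missing) > 0) {
    stop("schema error: pyramid is missing age band(s): ",
         paste(missing, collapse = ", "))
  }
  N <- pyramid[bands]
  if (any(N < 0)) stop("age-band populations must be non-negative")
  if (sum(N) == 0) stop("degenerate population: all age bands are zero")
  sum(N * recs) / sum(N)
}

#' Recommended-consumption target series for a world panel
#'
#' One (minimum, age-weighted) target pair per country-year for a given
#' scenario. The minimum target is constant (default 400 g/person/day);
#' the age-weighted target follows the scenario's population pyramid, so
#' it differs between scenarios only through demography. Years at or
#' before the panel's base year use the panel's single historical pyramid
#' and are flagged `historical`.
#'
#' @param world An `fv_world` panel.
#' @param scenario Scenario name present in the panel.
#' @param recs Age-band recommendation set.
#' @param minimum Flat minimum target in g/person/day (default 400).
#' @return data.frame: `country`, `year`, `scenario`, `historical`,
#'   `minimum_target`, `age_weighted_target`.
#' @export
target_series <- function(world, scenario, recs = default_recommendations(),
                          minimum = 400) {
  stopifnot(inherits(world, "fv_world"))
  if (!scenario %in% unique(world$population$scenario)) {
    stop("lookup error: unknown scenario '", scenario, "'; available: ",
         paste(unique(world$population$scenario), collapse = ", "))
  }
  pop <- world$population[world$population$scenario == scenario, ]
  tot <- pop$age_0_4 + pop$age_5_14 + pop$age_15plus
  if (any(tot <= 0)) stop("degenerate population in panel")
  R <- (pop$age_0_4 * recs[["age_0_4"]] +
        pop$age_5_14 * recs[["age_5_14"]] +
        pop$age_15plus * recs[["age_15plus"]]) / tot
  data.frame(
    country = pop$country,
    year = pop$year,
    scenario = scenario,
    historical = pop$year <= world$config$base_year,
    minimum_target = minimum,
    age_weighted_target = R,
    stringsAsFactors = FALSE
  )
}
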