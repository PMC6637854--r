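# Household-waste adjustment and gap/coverage summaries: availability ->
# waste-adjusted consumption -> comparison against the minimum and
# age-weighted targets, aggregated by region / income group / globally.

#' Define a household-waste scheme
#'
#' Three kinds are supported: `zero` (consumption equals availability),
#' `uniform` (a single share applied everywhere; 0.15 and 0.33 are the
#' conventional low/high stylised scenarios) and `regional` (a region ->
#' share lookup table, anchored by the FAO-style estimates of 5% for
#' sub-Saharan Africa and 28% for North America & Oceania).
#'
#' @param kind One of "zero", "uniform", "regional".
#' @param share Uniform waste share in \[0, 1); required for `uniform`.
#' @param table data.frame with columns `region`, `waste_share`; required
#'   for `regional`.
#' @param label Optional scheme label used in output tables.
#' @return Object of class `fv_waste_scheme`.
#' @export
#' @examples
#' waste_scheme("uniform", share = 0.33)
waste_scheme <- function(kind = c("zero", "uniform", "regional"),
                         share = NULL, table = NULL, label = NULL) {
  kind <- match.arg(kind)
  if (kind == "uniform") {
    if (is.null(share) || share < 0 || share >= 1) {
      stop("uniform scheme needs a share in [0, 1)")
    }
  }
  if (kind == "regional") {
    if (is.null(table) || !all(c("region", "waste_share") %in% names(table))) {
      stop("regional scheme needs a table with columns region, waste_share")
    }
    if (any(table$waste_share < 0 | table$waste_share >= 1)) {
      stop("regional waste shares must lie in [0, 1)")
    }
  }
  if (is.null(label)) {
    label <- switch(kind,
                    zero = "zero",
                    uniform = sprintf("uniform_%g", share),
                    regional = "regional")
  }
  structure(list(kind = kind, share = share, table = table, label = label),
            class = "fv_waste_scheme")
}

# waste share per observation, given regions (vectorised)
.waste_share <- function(scheme, region = NULL) {
  switch(scheme$kind,
         zero = 0,
         uniform = scheme$share,
         regional = {
           if (is.null(region)) {
             stop("lookup error: regional scheme requires region labels")
           }
           w <- scheme$table$waste_share[match(region, scheme$table$region)]
           if (anyNA(w)) {
             stop("lookup error: region(s) missing from waste table: ",
                  paste(unique(region[is.na(w)]), collapse = ", "))
           }
           w
         })
}

#' Apply a waste scheme to availability
#'
#' Consumption is `C = A * (1 - w)` with `w` the household waste share;
#' the zero scheme returns availability unchanged.
#'
#' @param availability Availability in g/person/day (vectorised), >= 0.
#' @param scheme An [waste_scheme()] object.
#' @param region Region labels aligned with `availability`; needed for
#'   regional schemes.
#' @return Waste-adjusted consumption in g/person/day.
#' @export
#' @examples
#' apply_waste(600, waste_scheme("uniform", share = 0.33)) # 402
apply_waste <- function(availability, scheme, region = NULL) {
  stopifnot(inherits(scheme, "fv_waste_scheme"))
  if (any(availability < 0)) stop("availability must be >= 0")
  availability * (1 - .waste_share(scheme, region))
}

#' Country-level gap table
#'
#' Joins availability with the target series, applies the waste scheme and
#' flags target attainment. Threshold comparisons are inclusive: a country
#' whose waste-adjusted consumption exactly equals the target passes.
#'
#' @param availability data.frame `country`, `year`, `scenario`,
#'   `availability` (as produced by [simulate_market()]).
#' @param targets data.frame from [target_series()].
#' @param scheme An [waste_scheme()].
#' @param countries data.frame `country`, `region` (and optionally
#'   `income_group`) mapping each country to its region.
#' @return data.frame of class `fv_gap`: one row per country-year with
#'   `availability`, `waste_share`, `consumption`, `ratio_min`,
#'   `ratio_age`, `pass_min`, `pass_age`.
#' @export
gap_table <- function(availability, targets, scheme, countries) {
  stopifnot(inherits(scheme, "fv_waste_scheme"))
  key <- function(d) paste(d$country, d$year, d$scenario, sep = "|")
  miss <- setdiff(key(availability), key(targets))
  if (length(miss) > 0) {
    stop("alignment error: targets missing for key(s): ",
         paste(head(miss, 5), collapse = ", "),
         if (length(miss) > 5) sprintf(" ... (%d total)", length(miss)))
  }
  g <- merge(availability, targets,
             by = c("country", "year", "scenario"), sort = TRUE)
  unmapped <- setdiff(g$country, countries$country)
  if (length(unmapped) > 0) {
    stop("grouping error: countries without region assignment: ",
         paste(unmapped, collapse = ", "))
  }
  g$region <- countries$region[match(g$country, countries$country)]
  g$waste_share <- rep_len(.waste_share(scheme, g$region), nrow(g))
  g$scheme <- scheme$label
  g$consumption <- g$availability * (1 - g$waste_share)
  g$ratio_min <- g$consumption / g$minimum_target
  g$ratio_age <- g$consumption / g$age_weighted_target
  g$pass_min <- g$consumption >= g$minimum_target
  g$pass_age <- g$consumption >= g$age_weighted_target
  class(g) <- c("fv_gap", "data.frame")
  g
}

#' Aggregate a gap table by region, income group, or globally
#'
#' Group availability and consumption are population-weighted means
#' (`sum(N * A) / sum(N)`); passing countries are counted and their
#' populations summed, for both the minimum and the age-weighted target.
#'
#' @param gap `fv_gap` table from [gap_table()].
#' @param world The `fv_world` panel supplying populations and group
#'   labels.
#' @param grouping One of "region", "income_group", "global".
#' @return data.frame with one row per group-year: weighted `availability`
#'   and `consumption`, `n_countries`, `n_pass_min`, `n_pass_age`,
#'   `population`, `pop_pass_min`, `pop_pass_age`.
#' @export
summarize_gap <- function(gap, world,
                          grouping = c("region", "income_group", "global")) {
  grouping <- match.arg(grouping)
  stopifnot(inherits(world, "fv_world"))
  pop <- world$population[, c("country", "year", "scenario", "total")]
  g <- merge(as.data.frame(gap), pop,
             by = c("country", "year", "scenario"), sort = TRUE)
  if (nrow(g) < nrow(gap)) {
    stop("alignment error: population missing for some gap rows")
  }
  g$group <- switch(
    grouping,
    global = "Global",
    region = g$region,
    income_group = {
      ig <- world$countries$income_group[match(g$country,
                                               world$countries$country)]
      if (anyNA(ig)) stop("grouping error: country without income group")
      ig
    })
  if (anyNA(g$group)) stop("grouping error: country without region")
  agg <- function(x, f) {
    aggregate(x, by = list(group = g$group, year = g$year,
                           scenario = g$scenario, scheme = g$scheme), FUN = f)
  }
  out <- agg(list(wA = g$availability * g$total), sum)
  out$wC <- agg(list(x = g$consumption * g$total), sum)$x
  out$population <- agg(list(x = g$total), sum)$x
  out$availability <- out$wA / out$population
  out$consumption <- out$wC / out$population
  out$n_countries <- agg(list(x = g$total), length)$x
  out$n_pass_min <- agg(list(x = g$pass_min), sum)$x
  out$n_pass_age <- agg(list(x = g$pass_age), sum)$x
  out$pop_pass_min <- agg(list(x = g$pass_min * g$total), sum)$x
  out$pop_pass_age <- agg(list(x = g$pass_age * g$total), sum)$x
  out$wA <- out$wC <- NULL
  out[order(out$group, out$year, out$scenario), , drop = FALSE]
}

#' Snapshot a gap summary at reporting years
#'
#' Convenience filter producing the classic five-year reporting view
#' (default 1965, 1990, 2015, 2030, 2050) of a gap or summary table.
#'
#' @param x data.frame with a `year` column.
#' @param years Snapshot years to keep.
#' @return Filtered data.frame.
#' @export
gap_snapshot <- function(x, years = c(1965, 1990, 2015, 2030, 2050)) {
  x[x$year %in% years, , drop = FALSE]
}
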