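# Synthetic world panels: seeded country-level population pyramids, income
# trajectories, base-year commodity balances with global trade closure,
# elasticities and exogenous supply growth, emulating the structure of
# FAO balance sheets + UN pyramids + SSP socioeconomic projections.

#' Socioeconomic scenario presets
#'
#' The three built-in scenario presets anchor global population and
#' per-capita GDP in 2050: SSP1 (optimistic/sustainable) at 8.5 billion
#' people and $34,000/person, SSP2 (middle-of-the-road) at 9.2 billion and
#' $25,000, SSP3 (fragmented/pessimistic) at 9.95 billion and $18,000.
#' The productivity multiplier scales exogenous supply growth so that more
#' optimistic scenarios also embody faster technical change.
#'
#' @return A data.frame with one row per preset: `name`,
#'   `global_population_2050` (persons), `global_gdp_per_capita_2050`
#'   (USD/person/year), `productivity_growth_multiplier`.
#' @export
#' @examples
#' ssp_presets()
ssp_presets <- function() {
  data.frame(
    name = c("SSP1", "SSP2", "SSP3"),
    global_population_2050 = c(8.5e9, 9.2e9, 9.95e9),
    global_gdp_per_capita_2050 = c(34000, 25000, 18000),
    productivity_growth_multiplier = c(1.2, 1.0, 0.8),
    stringsAsFactors = FALSE
  )
}

# FAO-style region list. Only the first two waste shares are anchored by
# published regional estimates (5% sub-Saharan Africa, 28% North America &
# Oceania); the rest default to the 15% placeholder.
.fv_region_names <- c(
  "sub-Saharan Africa",
  "North America & Oceania",
  "Europe",
  "Industrialised Asia",
  "South & Southeast Asia",
  "Latin America",
  "North Africa, West & Central Asia"
)

#' Default regional household-waste table
#'
#' Household (consumer) waste shares by region. The sub-Saharan Africa
#' (0.05) and North America & Oceania (0.28) entries reflect published FAO
#' regional estimates; all other regions carry a 0.15 placeholder that can
#' be edited before use.
#'
#' @param regions Character vector of region names; defaults to the seven
#'   built-in regions.
#' @return data.frame with columns `region`, `waste_share`.
#' @export
default_waste_table <- function(regions = .fv_region_names) {
  anchored <- c("sub-Saharan Africa" = 0.05, "North America & Oceania" = 0.28)
  w <- ifelse(regions %in% names(anchored), anchored[regions], 0.15)
  data.frame(region = regions, waste_share = unname(w), stringsAsFactors = FALSE)
}

#' Configuration for the synthetic world generator
#'
#' @param n_countries Number of countries (positive integer).
#' @param n_regions Number of regions; must not exceed `n_countries`.
#' @param base_year Calibration year dividing history from projection.
#' @param start_year,end_year Simulation horizon (start < base < end).
#' @param scenarios Character vector of preset names to generate; each must
#'   appear in `presets$name`.
#' @param commodities Commodity identifiers; the default follows the model
#'   aggregation of three fruit commodities plus one vegetable commodity.
#' @param elasticity_ranges List with elements `income` (bounds for the
#'   income elasticity of demand, positive), `price` (own-price elasticity,
#'   upper bound strictly negative) and `supply` (supply elasticity, lower
#'   bound strictly positive). The default ranges guarantee a unique market
#'   equilibrium because supply minus demand price response is positive.
#' @param base_population Global population in the base year (persons).
#' @param presets Scenario preset table, see [ssp_presets()].
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration.
#' @return An object of class `fv_world_config`.
#' @export
world_config <- function(n_countries = 20L,
                         n_regions = 7L,
                         base_year = 2010L,
                         start_year = 1961L,
                         end_year = 2050L,
                         scenarios = c("SSP1", "SSP2", "SSP3"),
                         commodities = c("fruit_temperate", "fruit_tropical",
                                         "fruit_citrus", "vegetables"),
                         elasticity_ranges = list(income = c(0.2, 1.0),
                                                  price = c(-0.8, -0.2),
                                                  supply = c(0.2, 0.8)),
                         base_population = 6.9e9,
                         presets = ssp_presets(),
                         seed = 1L) {
  if (!is.numeric(n_countries) || n_countries < 1) {
    stop("configuration error: n_countries must be a positive integer")
  }
  if (!is.numeric(n_regions) || n_regions < 1) {
    stop("configuration error: n_regions must be a positive integer")
  }
  if (n_regions > n_countries) {
    stop("configuration error: n_regions (", n_regions,
         ") must not exceed n_countries (", n_countries, ")")
  }
  if (!(start_year < base_year && base_year < end_year)) {
    stop("configuration error: need start_year < base_year < end_year, got ",
         start_year, " / ", base_year, " / ", end_year)
  }
  if (length(commodities) < 1) {
    stop("configuration error: at least one commodity is required")
  }
  er <- elasticity_ranges
  if (!all(c("income", "price", "supply") %in% names(er))) {
    stop("configuration error: elasticity_ranges needs income, price, supply")
  }
  if (max(er$price) >= 0) {
    stop("configuration error: own-price elasticity upper bound must be < 0")
  }
  if (min(er$supply) <= 0) {
    stop("configuration error: supply elasticity lower bound must be > 0")
  }
  missing_sc <- setdiff(scenarios, presets$name)
  if (length(missing_sc) > 0) {
    stop("configuration error: unknown scenario preset(s): ",
         paste(missing_sc, collapse = ", "))
  }
  structure(
    list(n_countries = as.integer(n_countries),
         n_regions = as.integer(n_regions),
         base_year = as.integer(base_year),
         start_year = as.integer(start_year),
         end_year = as.integer(end_year),
         scenarios = scenarios,
         commodities = commodities,
         elasticity_ranges = er,
         base_population = base_population,
         presets = presets[match(scenarios, presets$name), , drop = FALSE],
         seed = as.integer(seed)),
    class = "fv_world_config"
  )
}

#' Generate a synthetic world panel
#'
#' Draws a seeded multi-country world with the statistical structure the
#' downstream analysis assumes: age-banded population trajectories whose
#' 2050 global totals hit each scenario's anchor, log-linear per-capita
#' income paths rescaled so the population-weighted 2050 mean matches the
#' scenario GDP anchor, base-year commodity balances that close globally
#' (net trades sum to zero per commodity), Engel-consistent elasticities,
#' scenario-scaled exogenous supply growth, and a regional household-waste
#' table.
#'
#' Income heterogeneity is lognormal around $9,000/person (2010 global
#' per-capita GDP order of magnitude); base-year per-capita food demand is
#' centred near 400 g/person/day and scales with income to the 0.35 power,
#' reproducing the cross-sectional income gradient of fruit and vegetable
#' availability.
#'
#' @param config An [world_config()] object.
#' @return Object of class `fv_world`: a list of tidy data.frames
#'   (`countries`, `population`, `income`, `balances`, `elasticities`,
#'   `growth`, `waste`) plus the generating `config`.
#' @export
#' @examples
#' w <- generate_world(world_config(n_countries = 5, seed = 42))
#' head(w$balances)
generate_world <- function(config = world_config()) {
  if (!inherits(config, "fv_world_config")) {
    stop("configuration error: config must be created by world_config()")
  }
  withr::with_seed(config$seed, .generate_world_impl(config))
}

.generate_world_impl <- function(cfg) {
  n <- cfg$n_countries
  k <- length(cfg$commodities)
  years <- cfg$start_year:cfg$end_year
  ny <- length(years)
  anchor_year <- 2050L
  span <- anchor_year - cfg$base_year

  countries <- sprintf("C%02d", seq_len(n))
  region_names <- if (cfg$n_regions <= length(.fv_region_names)) {
    .fv_region_names[seq_len(cfg$n_regions)]
  } else {
    c(.fv_region_names,
      sprintf("Region %d", seq_len(cfg$n_regions - length(.fv_region_names))))
  }
  region <- sample(rep_len(region_names, n))

  ## ---- population ----
  w <- rlnorm(n, 0, 1.1)
  N0 <- w / sum(w) * cfg$base_population
  r_hist <- runif(n, 0.01, 0.03)          # historical growth, per year
  u <- rnorm(n, 0, 0.004)                 # country deviation from scenario mean

  # age-band shares in the base year; bands age over the projection
  s04_0 <- runif(n, 0.06, 0.16)
  s514_0 <- runif(n, 0.12, 0.26)

  ## ---- income ----
  y0 <- pmin(pmax(exp(rnorm(n, log(9000), 0.9)), 600), 60000)
  gy_hist <- runif(n, 0.01, 0.025)
  m_inc <- exp(rnorm(n, 0, 0.25))         # shared growth heterogeneity

  pop_list <- vector("list", length(cfg$scenarios))
  inc_list <- vector("list", length(cfg$scenarios))
  for (si in seq_along(cfg$scenarios)) {
    sc <- cfg$scenarios[si]
    pr <- cfg$presets[cfg$presets$name == sc, ]

    r_s <- log(pr$global_population_2050 / sum(N0)) / span
    raw2050 <- N0 * exp((r_s + u) * span)
    N2050 <- raw2050 * pr$global_population_2050 / sum(raw2050)
    gN <- log(N2050 / N0) / span

    # per-country totals, countries x years
    totals <- matrix(0, n, ny)
    for (j in seq_len(ny)) {
      t <- years[j]
      totals[, j] <- if (t <= cfg$base_year) {
        N0 * exp(-r_hist * (cfg$base_year - t))
      } else {
        N0 * exp(gN * (t - cfg$base_year))
      }
    }

    # aging: child shares shrink linearly to 70% of base by the anchor year
    f <- 1 - 0.3 * pmax(0, years - cfg$base_year) / span
    s04 <- outer(s04_0, f)
    s514 <- outer(s514_0, f)
    n04 <- totals * s04
    n514 <- totals * s514
    n15 <- totals - n04 - n514

    pop_list[[si]] <- data.frame(
      country = rep(countries, times = ny),
      year = rep(years, each = n),
      scenario = sc,
      age_0_4 = as.vector(n04),
      age_5_14 = as.vector(n514),
      age_15plus = as.vector(n15),
      total = as.vector(totals),
      stringsAsFactors = FALSE
    )

    # income: log-linear between base and a 2050 level rescaled so the
    # population-weighted global mean hits the preset anchor
    d_s <- sum(N2050 * m_inc * y0) / sum(N2050)
    y2050 <- (pr$global_gdp_per_capita_2050 / d_s) * m_inc * y0
    inc <- matrix(0, n, ny)
    for (j in seq_len(ny)) {
      t <- years[j]
      inc[, j] <- if (t <= cfg$base_year) {
        y0 * exp(-gy_hist * (cfg$base_year - t))
      } else {
        y0 * (y2050 / y0)^((t - cfg$base_year) / span)
      }
    }
    inc_list[[si]] <- data.frame(
      country = rep(countries, times = ny),
      year = rep(years, each = n),
      scenario = sc,
      income = as.vector(inc),
      stringsAsFactors = FALSE
    )
  }

  ## ---- base-year balances ----
  q <- pmin(pmax(400 * (y0 / median(y0))^0.35 * exp(rnorm(n, 0, 0.25)), 80), 900)
  food_tot <- q * N0 * 365 / 1e6          # tonnes/year

  shares <- matrix(rgamma(n * k, shape = 2, rate = 1), n, k)
  veg <- grepl("veg", cfg$commodities, ignore.case = TRUE)
  if (any(veg)) shares[, veg] <- shares[, veg] * 3
  shares <- shares / rowSums(shares)

  qd_food <- food_tot * shares
  qd_other <- qd_food * matrix(runif(n * k, 0.05, 0.25), n, k)
  qs_raw <- (qd_food + qd_other) * exp(matrix(rnorm(n * k, 0, 0.35), n, k))
  nt <- qs_raw - qd_food - qd_other
  # closure: rescale exporters' surpluses so net trades sum to zero
  for (i in seq_len(k)) {
    pos <- nt[, i] > 0
    s_plus <- sum(nt[pos, i])
    deficit <- -sum(nt[!pos, i])
    if (s_plus > 0 && deficit > 0) {
      nt[pos, i] <- nt[pos, i] * deficit / s_plus
    } else {
      nt[, i] <- 0
    }
  }
  qs <- qd_food + qd_other + nt

  balances <- data.frame(
    country = rep(countries, times = k),
    commodity = rep(cfg$commodities, each = n),
    production = as.vector(qs),
    food_demand = as.vector(qd_food),
    other_demand = as.vector(qd_other),
    net_trade = as.vector(nt),
    stringsAsFactors = FALSE
  )

  ## ---- elasticities: income elasticity declines with income (Engel) ----
  er <- cfg$elasticity_ranges
  rank01 <- if (n == 1) 0.5 else (rank(y0) - 1) / (n - 1)
  eps_y_c <- max(er$income) - diff(range(er$income)) * rank01
  eps_y <- pmin(pmax(eps_y_c + matrix(rnorm(n * k, 0, 0.05), n, k),
                     min(er$income)), max(er$income))
  eps_p <- matrix(runif(n * k, min(er$price), max(er$price)), n, k)
  gam <- matrix(runif(n * k, min(er$supply), max(er$supply)), n, k)

  elasticities <- data.frame(
    country = rep(countries, times = k),
    commodity = rep(cfg$commodities, each = n),
    income_elasticity = as.vector(eps_y),
    price_elasticity = as.vector(eps_p),
    supply_elasticity = as.vector(gam),
    stringsAsFactors = FALSE
  )

  ## ---- exogenous supply growth, scaled by the scenario multiplier ----
  g_base <- matrix(runif(n * k, 0.005, 0.02), n, k)
  growth <- do.call(rbind, lapply(seq_along(cfg$scenarios), function(si) {
    mult <- cfg$presets$productivity_growth_multiplier[si]
    data.frame(
      country = rep(countries, times = k),
      commodity = rep(cfg$commodities, each = n),
      scenario = cfg$scenarios[si],
      growth = as.vector(g_base * mult),
      stringsAsFactors = FALSE
    )
  }))

  income_group <- ifelse(y0 >= median(y0), "developed", "developing")

  structure(
    list(
      countries = data.frame(country = countries, region = region,
                             income_group = income_group,
                             stringsAsFactors = FALSE),
      population = do.call(rbind, pop_list),
      income = do.call(rbind, inc_list),
      balances = balances,
      elasticities = elasticities,
      growth = growth,
      waste = default_waste_table(region_names),
      config = cfg
    ),
    class = "fv_world"
  )
}

#' @export
print.fv_world <- function(x, ...) {
  cfg <- x$config
  cat("<fv_world> ", cfg$n_countries, " countries, ",
      length(cfg$commodities), " commodities, ",
      cfg$start_year, "-", cfg$end_year,
      " (base ", cfg$base_year, "), scenarios: ",
      paste(cfg$scenarios, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write / read a world panel as tidy CSV files
#'
#' Serialises the panel to `countries.csv`, `population.csv`, `income.csv`,
#' `balances.csv`, `elasticities.csv`, `growth.csv`, `waste.csv` and a
#' `world_config.json` holding the generating configuration. Output is
#' byte-identical for identical panels.
#'
#' @param world An `fv_world` object.
#' @param dir Output directory (created if missing).
#' @return `write_world_panel` invisibly returns the file paths;
#'   `read_world_panel` returns the reconstructed `fv_world`.
#' @export
write_world_panel <- function(world, dir) {
  stopifnot(inherits(world, "fv_world"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- c("countries", "population", "income", "balances",
            "elasticities", "growth", "waste")
  paths <- character(0)
  for (tb in tabs) {
    p <- file.path(dir, paste0(tb, ".csv"))
    write.csv(world[[tb]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  cfgp <- file.path(dir, "world_config.json")
  cfg <- world$config
  cfg_out <- unclass(cfg)
  jsonlite::write_json(cfg_out, cfgp, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(c(paths, cfgp))
}

#' @rdname write_world_panel
#' @export
read_world_panel <- function(dir) {
  cfg_raw <- jsonlite::read_json(file.path(dir, "world_config.json"),
                                 simplifyVector = TRUE)
  cfg <- world_config(
    n_countries = cfg_raw$n_countries, n_regions = cfg_raw$n_regions,
    base_year = cfg_raw$base_year, start_year = cfg_raw$start_year,
    end_year = cfg_raw$end_year, scenarios = cfg_raw$scenarios,
    commodities = cfg_raw$commodities,
    elasticity_ranges = lapply(cfg_raw$elasticity_ranges, as.numeric),
    base_population = cfg_raw$base_population,
    presets = as.data.frame(cfg_raw$presets, stringsAsFactors = FALSE),
    seed = cfg_raw$seed
  )
  out <- list(config = cfg)
  for (tb in c("countries", "population", "income", "balances",
               "elasticities", "growth", "waste")) {
    out[[tb]] <- read.csv(file.path(dir, paste0(tb, ".csv")),
                          stringsAsFactors = FALSE)
  }
  structure(out[c("countries", "population", "income", "balances",
                  "elasticities", "growth", "waste", "config")],
            class = "fv_world")
}

#' Default regional-bloc membership
#'
#' The three regional blocs used when expanding bloc-level policy records
#' to the country level: the EU with 28 member countries, the Caribbean
#' Community with 15, and the Pacific Island Nations and Territories group
#' with 22. Member codes are synthetic placeholders.
#'
#' @return Named list of character vectors (bloc name -> member codes).
#' @export
default_region_membership <- function() {
  list(
    "EU" = sprintf("EU%02d", 1:28),
    "Caribbean Community" = sprintf("CC%02d", 1:15),
    "Pacific Island Nations and Territories" = sprintf("PI%02d", 1:22)
  )
}

# description templates; the non-F&V set deliberately avoids both keywords
.fv_desc_templates <- c(
  "School scheme providing a minimum quantity of fruit daily",
  "Subsidy to reduce the retail price of vegetables",
  "Campaign promoting increased fruit and vegetable consumption",
  "Public procurement standard requiring fresh vegetable servings",
  "Voucher programme covering fruit purchases for low-income households"
)
.nonfv_desc_templates <- c(
  "Promote healthy eating through a mass-media campaign",
  "Front-of-pack nutrition labelling regulation",
  "Restrict marketing of energy-dense foods to children",
  "National strategy on balanced diets and active living",
  "Reformulation agreement reducing salt in processed foods"
)

#' Generate a synthetic policy database
#'
#' Emulates a database of implemented healthy-diet policy actions: each
#' record has a jurisdiction (a country code or one of the regional blocs),
#' a policy-taxonomy category with its domain, and a free-text description.
#' A configurable fraction of descriptions mention "fruit" or "vegetable"
#' and therefore satisfy the keyword targeting rule.
#'
#' @param n_records Number of records (positive integer).
#' @param seed Integer seed; output is deterministic per seed.
#' @param membership Bloc membership list, see [default_region_membership()];
#'   must define at least the three default blocs.
#' @param fv_fraction Probability that a record's description contains a
#'   fruit/vegetable keyword (default 0.22, the order of magnitude of the
#'   share of F&V-specific records in real policy databases).
#' @param countries Country codes used for country-level jurisdictions.
#' @param bloc_share Probability that a record is bloc-level.
#' @return data.frame with columns `id`, `jurisdiction`, `domain`,
#'   `category`, `description`.
#' @export
generate_policy_db <- function(n_records, seed = 1L,
                               membership = default_region_membership(),
                               fv_fraction = 0.22,
                               countries = sprintf("C%02d", 1:20),
                               bloc_share = 0.15) {
  if (!is.numeric(n_records) || length(n_records) != 1 || n_records < 1) {
    stop("n_records must be a positive integer")
  }
  need <- names(default_region_membership())
  if (!all(need %in% names(membership))) {
    stop("membership must define at least the blocs: ",
         paste(need, collapse = "; "))
  }
  if (fv_fraction < 0 || fv_fraction > 1) stop("fv_fraction must lie in [0, 1]")
  tax <- nourishing_taxonomy()
  withr::with_seed(seed, {
    n <- as.integer(n_records)
    is_bloc <- runif(n) < bloc_share
    jur <- character(n)
    jur[is_bloc] <- sample(names(membership), sum(is_bloc), replace = TRUE)
    jur[!is_bloc] <- sample(countries, sum(!is_bloc), replace = TRUE)
    row <- sample(nrow(tax), n, replace = TRUE)
    hit <- runif(n) < fv_fraction
    desc <- character(n)
    desc[hit] <- sample(.fv_desc_templates, sum(hit), replace = TRUE)
    desc[!hit] <- sample(.nonfv_desc_templates, sum(!hit), replace = TRUE)
    data.frame(
      id = sprintf("P%04d", seq_len(n)),
      jurisdiction = jur,
      domain = tax$domain[row],
      category = tax$category[row],
      description = desc,
      stringsAsFactors = FALSE
    )
  })
}
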