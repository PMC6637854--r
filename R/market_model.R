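# Simplified partial-equilibrium multimarket simulator.
#
# Demand and supply are constant-elasticity (log-linear) in prices and
# income; each commodity trades on a single integrated world market whose
# price is solved so that global supply equals global demand. Dynamics are
# recursive-annual: exogenous drivers (population, income, supply growth)
# update each year and the market is re-cleared. Post-harvest losses are
# folded into the calibrated supply intercept; processing/storage losses
# live in "other demand", a calibrated proportional share of food demand.

#' Construct market parameters
#'
#' Low-level constructor used for hand-built toy markets; panels are
#' normally calibrated with [calibrate()]. All matrix arguments are
#' country x commodity.
#'
#' @param alpha Per-capita food-demand intercepts at base prices/income
#'   (tonnes/year per person), non-negative.
#' @param beta Supply intercepts (tonnes/year at base prices), non-negative.
#' @param lambda Other-demand shares (other demand / food demand), >= 0.
#' @param eps_y,eps_p,gamma Income, own-price and supply elasticities;
#'   `eps_p < 0 < gamma` is required wherever `beta > 0` so that world
#'   excess demand is strictly monotone and the equilibrium unique.
#' @param y0 Base-year per-capita income by country (USD/person/year).
#' @param N0 Base-year population by country (persons).
#' @param base_year Calibration year.
#' @param growth Optional country x commodity x scenario array of annual
#'   exogenous supply growth rates.
#' @param countries,commodities Identifier vectors (default from dimnames).
#' @return Object of class `fv_market_params`.
#' @export
market_params <- function(alpha, beta, lambda, eps_y, eps_p, gamma,
                          y0, N0, base_year,
                          growth = NULL,
                          countries = rownames(alpha),
                          commodities = colnames(alpha)) {
  if (is.null(countries)) countries <- sprintf("C%02d", seq_len(nrow(alpha)))
  if (is.null(commodities)) commodities <- sprintf("K%d", seq_len(ncol(alpha)))
  dn <- list(countries, commodities)
  fix <- function(m) {
    m <- as.matrix(m)
    dimnames(m) <- dn
    m
  }
  alpha <- fix(alpha); beta <- fix(beta); lambda <- fix(lambda)
  eps_y <- fix(eps_y); eps_p <- fix(eps_p); gamma <- fix(gamma)
  if (any(alpha < 0) || any(beta < 0)) stop("alpha and beta must be >= 0")
  if (any(lambda < 0)) stop("lambda must be >= 0")
  active <- beta > 0 | alpha > 0
  if (any(eps_p[active] >= 0)) stop("own-price elasticity must be < 0")
  if (any(gamma[beta > 0] <= 0)) stop("supply elasticity must be > 0 where beta > 0")
  if (any(y0 <= 0) || any(N0 <= 0)) stop("y0 and N0 must be positive")
  structure(
    list(alpha = alpha, beta = beta, lambda = lambda,
         eps_y = eps_y, eps_p = eps_p, gamma = gamma,
         y0 = setNames(as.numeric(y0), countries),
         N0 = setNames(as.numeric(N0), countries),
         base_year = as.integer(base_year),
         growth = growth,
         countries = countries, commodities = commodities),
    class = "fv_market_params"
  )
}

#' Calibrate market parameters to a world panel's base year
#'
#' With base-year drivers and all prices at the base index of 1, the
#' calibrated model reproduces the panel's base balances exactly:
#' `alpha = food_demand0 / N0`, `lambda = other_demand0 / food_demand0`
#' (zero when both are zero), `beta = production0`.
#'
#' @param world An `fv_world` panel.
#' @return `fv_market_params`.
#' @export
calibrate <- function(world) {
  stopifnot(inherits(world, "fv_world"))
  cfg <- world$config
  ctry <- world$countries$country
  comm <- cfg$commodities
  bal <- world$balances
  idx <- cbind(match(bal$country, ctry), match(bal$commodity, comm))
  mat <- function(col) {
    m <- matrix(0, length(ctry), length(comm), dimnames = list(ctry, comm))
    m[idx] <- bal[[col]]
    m
  }
  qs0 <- mat("production")
  qf0 <- mat("food_demand")
  qo0 <- mat("other_demand")

  bad <- qf0 == 0 & qo0 > 0
  if (any(bad)) {
    who <- which(bad, arr.ind = TRUE)
    stop("calibration error: other demand without food demand (lambda ",
         "undefined) for ", ctry[who[1, 1]], " / ", comm[who[1, 2]])
  }
  lambda <- ifelse(qf0 > 0, qo0 / qf0, 0)

  sc1 <- cfg$scenarios[1]
  popb <- world$population[world$population$scenario == sc1 &
                           world$population$year == cfg$base_year, ]
  incb <- world$income[world$income$scenario == sc1 &
                       world$income$year == cfg$base_year, ]
  N0 <- setNames(popb$total[match(ctry, popb$country)], ctry)
  y0 <- setNames(incb$income[match(ctry, incb$country)], ctry)

  el <- world$elasticities
  eidx <- cbind(match(el$country, ctry), match(el$commodity, comm))
  emat <- function(col) {
    m <- matrix(NA_real_, length(ctry), length(comm),
                dimnames = list(ctry, comm))
    m[eidx] <- el[[col]]
    m
  }

  gr <- world$growth
  growth <- array(0, dim = c(length(ctry), length(comm), length(cfg$scenarios)),
                  dimnames = list(ctry, comm, cfg$scenarios))
  growth[cbind(match(gr$country, ctry), match(gr$commodity, comm),
               match(gr$scenario, cfg$scenarios))] <- gr$growth

  market_params(
    alpha = qf0 / N0, beta = qs0, lambda = lambda,
    eps_y = emat("income_elasticity"),
    eps_p = emat("price_elasticity"),
    gamma = emat("supply_elasticity"),
    y0 = y0, N0 = N0, base_year = cfg$base_year,
    growth = growth, countries = ctry, commodities = comm
  )
}

# cumulative exogenous growth factor Prod_{s>base}(1+g) per country, for
# one commodity; 1 for the base year and for scenario-free toys
.growth_factor <- function(params, i, year, scenario) {
  if (is.null(scenario) || is.null(params$growth) ||
      year <= params$base_year) {
    return(rep(1, length(params$countries)))
  }
  g <- params$growth[, i, scenario]
  (1 + g)^(year - params$base_year)
}

.check_price <- function(price) {
  if (any(!is.finite(price)) || any(price <= 0)) {
    stop("domain error: price must be strictly positive")
  }
}

# vectorised country-level food demand for commodity i at world price P;
# cross_mult is an optional scalar multiplier from cross-price terms
.qd_food_vec <- function(params, i, N, y, price, cross_mult = 1) {
  params$alpha[, i] * N * (y / params$y0)^params$eps_y[, i] *
    price^params$eps_p[, i] * cross_mult
}

.qs_vec <- function(params, i, price, gf) {
  params$beta[, i] * price^params$gamma[, i] * gf
}

#' Food demand for one country-commodity
#'
#' Constant-elasticity demand
#' `QD_food = alpha * N * (y/y0)^eps_y * P^eps_p` (tonnes/year); other
#' demand is the calibrated proportional share `lambda * QD_food`.
#'
#' @param params `fv_market_params`.
#' @param country,commodity Identifiers.
#' @param N Population (persons), `y` per-capita income (USD/person/year).
#' @param price World price index (base = 1), strictly positive.
#' @param y Per-capita income.
#' @return Food demand in tonnes/year.
#' @export
demand_quantity <- function(params, country, commodity, N, y, price) {
  .check_price(price)
  if (N <= 0 || y <= 0) stop("domain error: N and y must be positive")
  i <- match(commodity, params$commodities)
  c <- match(country, params$countries)
  if (is.na(i) || is.na(c)) stop("unknown country or commodity")
  unname(params$alpha[c, i] * N * (y / params$y0[c])^params$eps_y[c, i] *
           price^params$eps_p[c, i])
}

#' Supply for one country-commodity
#'
#' `QS = beta * P^gamma * prod(1+g)` with the growth product running over
#' post-base years; years at or before the base year carry no growth.
#'
#' @inheritParams demand_quantity
#' @param year Calendar year.
#' @param scenario Scenario name indexing the growth array; `NULL` for
#'   growth-free toys.
#' @return Supply in tonnes/year.
#' @export
supply_quantity <- function(params, country, commodity, year, scenario = NULL,
                            price = 1) {
  .check_price(price)
  i <- match(commodity, params$commodities)
  c <- match(country, params$countries)
  if (is.na(i) || is.na(c)) stop("unknown country or commodity")
  gf <- .growth_factor(params, i, year, scenario)[c]
  unname(params$beta[c, i] * price^params$gamma[c, i] * gf)
}

#' World excess demand for one commodity
#'
#' `E(P) = sum_c [QD_food + QD_other] - sum_c QS`, strictly decreasing in
#' the world price under the maintained sign restrictions, so a sign
#' change brackets the unique equilibrium.
#'
#' @inheritParams demand_quantity
#' @param N,y Per-country driver vectors aligned with `params$countries`.
#' @param year,scenario Growth indexing, as in [supply_quantity()].
#' @return Excess demand in tonnes/year.
#' @export
world_excess_demand <- function(params, commodity, N, y, price,
                                year = params$base_year, scenario = NULL) {
  .check_price(price)
  i <- match(commodity, params$commodities)
  if (is.na(i)) stop("unknown commodity: ", commodity)
  gf <- .growth_factor(params, i, year, scenario)
  qf <- .qd_food_vec(params, i, N, y, price)
  sum(qf * (1 + params$lambda[, i])) - sum(.qs_vec(params, i, price, gf))
}

# bracketed root finding on strictly decreasing f; NA if no sign change
# inside the configured bounds
.solve_price <- function(f, bounds, tol) {
  lo <- max(0.25, bounds[1]); hi <- min(4, bounds[2])
  flo <- f(lo); fhi <- f(hi)
  while (flo < 0 && lo > bounds[1]) {
    lo <- max(lo / 4, bounds[1]); flo <- f(lo)
  }
  while (fhi > 0 && hi < bounds[2]) {
    hi <- min(hi * 4, bounds[2]); fhi <- f(hi)
  }
  if (flo == 0) return(lo)
  if (fhi == 0) return(hi)
  if (flo < 0 || fhi > 0) return(NA_real_)
  uniroot(f, c(lo, hi), f.lower = flo, f.upper = fhi, tol = tol)$root
}

#' Solve one year's market equilibrium
#'
#' Finds, for every commodity, the world price at which global supply
#' equals global demand. With own-price effects only (the default) the
#' commodities are separable and each price is found by Brent-style
#' bracketed root finding on the strictly monotone excess demand, with the
#' initial bracket \[0.25, 4\] expanded geometrically up to `price_bounds`.
#' With a cross-price elasticity matrix the solver switches to damped
#' fixed-point iteration on the price vector.
#'
#' @param params `fv_market_params`.
#' @param drivers List with per-country vectors `N` (persons) and `y`
#'   (USD/person/year), aligned with `params$countries`.
#' @param year Calendar year (drives the exogenous growth product).
#' @param scenario Scenario name, or `NULL` for growth-free toys.
#' @param cross Optional commodity x commodity cross-price elasticity
#'   matrix (diagonal ignored; own-price elasticities stay in `params`).
#' @param price_bounds Hard bracket bounds (default `c(1e-3, 1e3)`).
#' @param tol Root-finding tolerance on the price.
#' @param damping,max_iter,cross_tol Fixed-point controls used only when
#'   `cross` is supplied.
#' @return List with named `prices`, absolute clearing `residuals`, total
#'   world `supply_total` per commodity, and country x commodity matrices
#'   `supply`, `food_demand`, `other_demand`, `net_trade`.
#' @export
solve_year <- function(params, drivers, year, scenario = NULL,
                       cross = NULL, price_bounds = c(1e-3, 1e3),
                       tol = 1e-12, damping = 0.5, max_iter = 500,
                       cross_tol = 1e-8) {
  stopifnot(inherits(params, "fv_market_params"))
  N <- rep_len(drivers$N, length(params$countries))
  y <- rep_len(drivers$y, length(params$countries))
  if (any(N <= 0) || any(y <= 0)) stop("domain error: drivers must be positive")
  K <- length(params$commodities)
  prices <- setNames(rep(1, K), params$commodities)

  cross_mult <- function(i, P) {
    if (is.null(cross)) return(1)
    j <- setdiff(seq_len(K), i)
    prod(P[j]^cross[i, j])
  }

  solve_pass <- function(P_fixed) {
    out <- P_fixed
    for (i in seq_len(K)) {
      if (sum(params$alpha[, i] * N) == 0 && sum(params$beta[, i]) == 0) {
        out[i] <- 1  # empty market: price conventionally at base index
        next
      }
      gf <- .growth_factor(params, i, year, scenario)
      cm <- cross_mult(i, P_fixed)
      f <- function(P) {
        qf <- .qd_food_vec(params, i, N, y, P, cm)
        sum(qf * (1 + params$lambda[, i])) - sum(.qs_vec(params, i, P, gf))
      }
      root <- .solve_price(f, price_bounds, tol)
      if (is.na(root)) {
        stop("non-convergence: no market-clearing price for commodity '",
             params$commodities[i], "' in year ", year,
             " within price bounds [", price_bounds[1], ", ",
             price_bounds[2], "]; residual at bounds: ",
             signif(f(price_bounds[1]), 6), " / ",
             signif(f(price_bounds[2]), 6))
      }
      out[i] <- root
    }
    out
  }

  if (is.null(cross)) {
    prices <- solve_pass(prices)
  } else {
    for (it in seq_len(max_iter)) {
      target <- solve_pass(prices)
      new <- (1 - damping) * prices + damping * target
      delta <- max(abs(new - prices) / pmax(prices, 1e-12))
      prices <- new
      if (delta < cross_tol) break
      if (it == max_iter) {
        stop("non-convergence: cross-price fixed point did not settle in ",
             max_iter, " iterations (year ", year, ", max rel change ",
             signif(delta, 4), ")")
      }
    }
    prices <- solve_pass(prices)  # final exact clearing given settled vector
  }

  n <- length(params$countries)
  food <- other <- supp <- matrix(
    0, n, K, dimnames = list(params$countries, params$commodities))
  residuals <- supply_total <- setNames(numeric(K), params$commodities)
  for (i in seq_len(K)) {
    gf <- .growth_factor(params, i, year, scenario)
    cm <- cross_mult(i, prices)
    food[, i] <- .qd_food_vec(params, i, N, y, prices[i], cm)
    other[, i] <- food[, i] * params$lambda[, i]
    supp[, i] <- .qs_vec(params, i, prices[i], gf)
    supply_total[i] <- sum(supp[, i])
    residuals[i] <- sum(food[, i] + other[, i]) - supply_total[i]
  }
  list(prices = prices, residuals = residuals, supply_total = supply_total,
       supply = supp, food_demand = food, other_demand = other,
       net_trade = supp - food - other)
}

#' Simulate a scenario over the panel horizon
#'
#' Recursive-dynamic annual solution. Years strictly before the base year
#' replay the panel's base balances at the base price index (history is
#' data, not model); the base year and later years are solved by market
#' clearing. Per-capita fruit-and-vegetable availability is
#' `A = sum_i QD_food(c, i) * 1e6 / (N(c) * 365)` in g/person/day.
#'
#' @param world An `fv_world` panel.
#' @param scenario Scenario name present in the panel.
#' @param years Years to simulate (default: the panel horizon).
#' @param cross,price_bounds,tol Passed to [solve_year()].
#' @return Object of class `fv_equilibrium`: list of data.frames `prices`
#'   (year, commodity, price, residual, supply_total), `balances`
#'   (year, country, commodity, supply, food_demand, other_demand,
#'   net_trade) and `availability` (country, year, availability in
#'   g/person/day), all carrying the scenario.
#' @export
simulate_market <- function(world, scenario, years = NULL, cross = NULL,
                            price_bounds = c(1e-3, 1e3), tol = 1e-12) {
  stopifnot(inherits(world, "fv_world"))
  cfg <- world$config
  if (!scenario %in% cfg$scenarios) {
    stop("lookup error: unknown scenario '", scenario, "'")
  }
  if (is.null(years)) years <- cfg$start_year:cfg$end_year
  if (any(years < cfg$start_year | years > cfg$end_year)) {
    stop("years outside the panel horizon ", cfg$start_year, "-", cfg$end_year)
  }
  params <- calibrate(world)
  ctry <- params$countries
  comm <- params$commodities
  n <- length(ctry); K <- length(comm)

  pop <- world$population[world$population$scenario == scenario &
                          world$population$year %in% years, ]
  inc <- world$income[world$income$scenario == scenario &
                      world$income$year %in% years, ]
  Npop <- matrix(NA_real_, n, length(years), dimnames = list(ctry, years))
  Yinc <- Npop
  Npop[cbind(match(pop$country, ctry), match(pop$year, years))] <- pop$total
  Yinc[cbind(match(inc$country, ctry), match(inc$year, years))] <- inc$income
  keep <- colnames(Npop)[colSums(is.na(Npop)) == 0]
  if (length(keep) < length(years)) {
    stop("panel is missing drivers for year(s): ",
         paste(setdiff(as.character(years), keep), collapse = ", "))
  }

  base_food <- base_other <- base_supp <- matrix(
    0, n, K, dimnames = list(ctry, comm))
  bal <- world$balances
  bidx <- cbind(match(bal$country, ctry), match(bal$commodity, comm))
  base_supp[bidx] <- bal$production
  base_food[bidx] <- bal$food_demand
  base_other[bidx] <- bal$other_demand

  price_rows <- vector("list", length(years))
  bal_rows <- vector("list", length(years))
  avail_rows <- vector("list", length(years))
  for (j in seq_along(years)) {
    yr <- years[j]
    if (yr < cfg$base_year) {
      sol <- list(
        prices = setNames(rep(1, K), comm),
        supply_total = colSums(base_supp),
        residuals = colSums(base_food + base_other) - colSums(base_supp),
        supply = base_supp, food_demand = base_food,
        other_demand = base_other,
        net_trade = base_supp - base_food - base_other)
    } else {
      sol <- tryCatch(
        solve_year(params, list(N = Npop[, j], y = Yinc[, j]), yr,
                   scenario = scenario, cross = cross,
                   price_bounds = price_bounds, tol = tol),
        error = function(e) {
          stop("simulation failed in year ", yr, " (", scenario, "): ",
               conditionMessage(e))
        })
    }
    price_rows[[j]] <- data.frame(
      year = yr, scenario = scenario, commodity = comm,
      price = unname(sol$prices), residual = unname(sol$residuals),
      supply_total = unname(sol$supply_total), stringsAsFactors = FALSE)
    bal_rows[[j]] <- data.frame(
      year = yr, scenario = scenario,
      country = rep(ctry, times = K), commodity = rep(comm, each = n),
      supply = as.vector(sol$supply),
      food_demand = as.vector(sol$food_demand),
      other_demand = as.vector(sol$other_demand),
      net_trade = as.vector(sol$net_trade), stringsAsFactors = FALSE)
    avail_rows[[j]] <- data.frame(
      country = ctry, year = yr, scenario = scenario,
      availability = rowSums(sol$food_demand) * 1e6 / (Npop[, j] * 365),
      stringsAsFactors = FALSE)
  }
  structure(
    list(prices = do.call(rbind, price_rows),
         balances = do.call(rbind, bal_rows),
         availability = do.call(rbind, avail_rows),
         scenario = scenario,
         settings = list(price_bounds = price_bounds, tol = tol,
                         cross = !is.null(cross))),
    class = "fv_equilibrium"
  )
}

#' @export
print.fv_equilibrium <- function(x, ...) {
  yrs <- range(x$prices$year)
  cat("<fv_equilibrium> scenario ", x$scenario, ", years ", yrs[1], "-",
      yrs[2], ", max |residual|/supply = ",
      signif(max(abs(x$prices$residual) / pmax(x$prices$supply_total, 1)), 3),
      "\n", sep = "")
  invisible(x)
}
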