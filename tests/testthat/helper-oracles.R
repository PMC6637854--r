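# Independent oracles and small fixture builders used across the suite.

# plain bisection on a strictly decreasing function; independent of the
# package's Brent-based solver
bisect_price <- function(f, lower, upper, iters = 60) {
  fl <- f(lower)
  fu <- f(upper)
  stopifnot(fl > 0, fu < 0)
  for (i in seq_len(iters)) {
    mid <- (lower + upper) / 2
    if (f(mid) > 0) lower <- mid else upper <- mid
  }
  (lower + upper) / 2
}

# brute-force age-weighted recommendation: one entry per individual
brute_force_target <- function(counts, recs = default_recommendations()) {
  mean(rep(recs[names(counts)], counts))
}

# compact seeded world for fast unit tests
small_world <- function(seed = 1, n_countries = 6, n_regions = 3,
                        start_year = 2000, end_year = 2030) {
  generate_world(world_config(
    n_countries = n_countries, n_regions = n_regions,
    base_year = 2010, start_year = start_year, end_year = end_year,
    seed = seed))
}

# hand-built single-country, single-commodity panel with explicit balances
# (net trade forced to zero, so production = food + other)
mini_world <- function(food = 120, other = 30, N0 = 1e6, y0 = 1000,
                       eps_y = 0.5, eps_p = -0.5, gamma = 0.5,
                       growth = 0, years = 2009:2015, base_year = 2010,
                       scenario = "SSP2") {
  cfg <- world_config(n_countries = 1, n_regions = 1,
                      base_year = base_year, start_year = min(years),
                      end_year = max(years), scenarios = scenario,
                      commodities = "fv", seed = 1)
  ny <- length(years)
  structure(list(
    countries = data.frame(country = "C01", region = "sub-Saharan Africa",
                           income_group = "developing",
                           stringsAsFactors = FALSE),
    population = data.frame(country = "C01", year = years,
                            scenario = scenario, age_0_4 = 0, age_5_14 = 0,
                            age_15plus = N0, total = N0,
                            stringsAsFactors = FALSE),
    income = data.frame(country = "C01", year = years, scenario = scenario,
                        income = y0, stringsAsFactors = FALSE),
    balances = data.frame(country = "C01", commodity = "fv",
                          production = food + other, food_demand = food,
                          other_demand = other, net_trade = 0,
                          stringsAsFactors = FALSE),
    elasticities = data.frame(country = "C01", commodity = "fv",
                              income_elasticity = eps_y,
                              price_elasticity = eps_p,
                              supply_elasticity = gamma,
                              stringsAsFactors = FALSE),
    growth = data.frame(country = "C01", commodity = "fv",
                        scenario = scenario, growth = growth,
                        stringsAsFactors = FALSE),
    waste = default_waste_table(),
    config = cfg), class = "fv_world")
}

# homogeneous one-commodity toy market with a closed-form equilibrium:
# demand k*S0*P^eps_p against supply S0*P^gamma clears at P = k^(1/(gamma-eps_p))
toy_params <- function(S0 = 1000, eps_y = 0.5, eps_p = -0.5, gamma = 0.5,
                       N0 = 1e6, y0 = 1000) {
  market_params(alpha = matrix(S0 / N0), beta = matrix(S0),
                lambda = matrix(0), eps_y = matrix(eps_y),
                eps_p = matrix(eps_p), gamma = matrix(gamma),
                y0 = y0, N0 = N0, base_year = 2010,
                countries = "C01", commodities = "fv")
}

# random multi-country single-commodity market for solver/oracle checks;
# supply intercepts are scaled to a moderate demand/supply imbalance so the
# equilibrium price stays inside the solver's hard bounds
random_market <- function() {
  n <- sample(1:5, 1)
  alpha <- runif(n, 1e-4, 1e-2)
  lambda <- runif(n, 0, 0.3)
  y0 <- runif(n, 500, 20000)
  N0 <- runif(n, 1e5, 1e8)
  N <- N0 * runif(n, 0.5, 2)
  y <- y0 * runif(n, 0.5, 2)
  eps_y <- runif(n, 0.2, 1.0)
  base_dem <- sum(alpha * N * (y / y0)^eps_y * (1 + lambda))
  beta <- base_dem * exp(runif(1, -1.5, 1.5)) * runif(n)
  beta <- beta / sum(beta) * base_dem * exp(runif(1, -1.5, 1.5))
  params <- market_params(
    alpha = matrix(alpha, n, 1), beta = matrix(beta, n, 1),
    lambda = matrix(lambda, n, 1), eps_y = matrix(eps_y, n, 1),
    eps_p = matrix(runif(n, -0.8, -0.2), n, 1),
    gamma = matrix(runif(n, 0.2, 0.8), n, 1),
    y0 = y0, N0 = N0, base_year = 2010,
    countries = sprintf("C%02d", seq_len(n)), commodities = "fv")
  list(params = params, N = N, y = y)
}

# population-weighted global mean availability at one year
global_availability <- function(sim, world, year) {
  a <- sim$availability[sim$availability$year == year, ]
  p <- world$population[world$population$year == year &
                        world$population$scenario == sim$scenario, ]
  w <- p$total[match(a$country, p$country)]
  sum(a$availability * w) / sum(w)
}
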