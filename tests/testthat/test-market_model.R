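test_that("calibration reproduces base balances through the solver", {
  w <- small_world(seed = 4)
  params <- calibrate(w)
  pop <- w$population[w$population$scenario == "SSP2" &
                      w$population$year == 2010, ]
  inc <- w$income[w$income$scenario == "SSP2" & w$income$year == 2010, ]
  sol <- solve_year(params,
                    list(N = pop$total[match(params$countries, pop$country)],
                         y = inc$income[match(params$countries, inc$country)]),
                    2010, scenario = "SSP2")
  expect_equal(unname(sol$prices), rep(1, 4), tolerance = 1e-9)
  bal <- w$balances
  idx <- cbind(match(bal$country, params$countries),
               match(bal$commodity, params$commodities))
  expect_equal(sol$food_demand[idx], bal$food_demand, tolerance = 1e-9)
  expect_equal(sol$supply[idx], bal$production, tolerance = 1e-9)
  expect_equal(sol$other_demand[idx], bal$other_demand, tolerance = 1e-9)
})

test_that("calibrated shares follow the ratio oracle", {
  w <- mini_world(food = 120, other = 30)
  params <- calibrate(w)
  expect_equal(unname(params$lambda[1, 1]), 30 / 120)
  expect_equal(unname(params$alpha[1, 1]), 120 / 1e6)
  expect_equal(unname(params$beta[1, 1]), 150)
})

test_that("other demand without food demand is a calibration error", {
  w <- mini_world(food = 0, other = 30)
  expect_error(calibrate(w), "calibration error")
})

test_that("demand follows its constant-elasticity closed forms", {
  w <- mini_world(eps_y = 0.5, eps_p = -0.5)
  params <- calibrate(w)
  base <- demand_quantity(params, "C01", "fv", N = 1e6, y = 1000, price = 1)
  expect_equal(base, 120, tolerance = 1e-12)
  # eps_y = 0.5, y = 4*y0: per-capita demand doubles (4^0.5 = 2)
  expect_equal(demand_quantity(params, "C01", "fv", 1e6, 4000, 1), 240,
               tolerance = 1e-12)
  # eps_p = -0.5, P = 4: demand halves (4^-0.5 = 0.5)
  expect_equal(demand_quantity(params, "C01", "fv", 1e6, 1000, 4), 60,
               tolerance = 1e-12)
  # proportional in N
  expect_equal(demand_quantity(params, "C01", "fv", 2e6, 1000, 1), 240,
               tolerance = 1e-12)
  expect_error(demand_quantity(params, "C01", "fv", 1e6, 1000, -1),
               "domain error")
})

test_that("supply follows its price response and compound growth", {
  w <- mini_world(gamma = 0.5, growth = 0.02)
  params <- calibrate(w)
  expect_equal(supply_quantity(params, "C01", "fv", 2010, "SSP2", price = 1),
               150, tolerance = 1e-12)
  # 10 years of 2% growth at fixed price: QS0 * 1.02^10
  w10 <- mini_world(growth = 0.02, years = 2009:2020)
  p10 <- calibrate(w10)
  expect_equal(supply_quantity(p10, "C01", "fv", 2020, "SSP2", price = 1),
               150 * 1.02^10, tolerance = 1e-12)
  # increasing in price
  expect_gt(supply_quantity(params, "C01", "fv", 2010, "SSP2", price = 2),
            supply_quantity(params, "C01", "fv", 2010, "SSP2", price = 1))
  # beta = 0 pins supply at zero for any price
  zp <- toy_params(S0 = 1000)
  zp$beta[1, 1] <- 0
  expect_identical(supply_quantity(zp, "C01", "fv", 2010, price = 7), 0)
})

test_that("the homogeneous toy clears at its closed-form price", {
  params <- toy_params(S0 = 1000, eps_p = -0.5, gamma = 0.5, eps_y = 0.5)
  # demand shifter k = 2 via income: (4*y0/y0)^0.5 = 2; P* = k^(1/(gamma-eps_p)) = 2
  drv <- list(N = 1e6, y = 4000)
  sol <- solve_year(params, drv, 2010)
  expect_equal(unname(sol$prices), 2, tolerance = 1e-8)
  expect_equal(unname(sol$supply_total), 1000 * sqrt(2), tolerance = 1e-8)
  # excess demand at the solved price is below tolerance, positive as P -> 0
  expect_lt(abs(world_excess_demand(params, "fv", 1e6, 4000, sol$prices[[1]])),
            1e-6)
  expect_gt(world_excess_demand(params, "fv", 1e6, 4000, 1e-6), 0)
})

test_that("solver agrees with a 60-iteration bisection oracle", {
  set.seed(77)
  for (i in 1:25) {
    mk <- random_market()
    sol <- solve_year(mk$params, list(N = mk$N, y = mk$y), 2010)
    f <- function(P) world_excess_demand(mk$params, "fv", mk$N, mk$y, P)
    oracle <- bisect_price(f, 1e-3, 1e3)
    expect_equal(unname(sol$prices[[1]]), oracle, tolerance = 1e-8)
  }
})

test_that("world excess demand is strictly decreasing in price", {
  set.seed(5)
  mk <- random_market()
  grid <- exp(seq(log(0.01), log(100), length.out = 40))
  E <- vapply(grid, function(P) {
    world_excess_demand(mk$params, "fv", mk$N, mk$y, P)
  }, numeric(1))
  expect_true(all(diff(E) < 0))
})

test_that("a root outside the price bounds raises a non-convergence error", {
  params <- toy_params(eps_y = 1, eps_p = -0.5, gamma = 0.5)
  # demand shifter 1e30 puts the closed-form root at 1e30 >> upper bound
  expect_error(solve_year(params, list(N = 1e6, y = 1000 * 1e30), 2010),
               "non-convergence")
})

test_that("zero growth and constant drivers give a steady state", {
  w <- mini_world(growth = 0, years = 2009:2015)
  sim <- simulate_market(w, "SSP2")
  expect_true(all(abs(sim$prices$price - 1) < 1e-9))
  expect_true(all(abs(sim$balances$food_demand - 120) < 1e-7))
  expect_true(all(abs(sim$balances$supply - 150) < 1e-7))
  # availability constant: 120 t/yr over 1e6 people
  expect_equal(sim$availability$availability,
               rep(120 * 1e6 / (1e6 * 365), 7), tolerance = 1e-9)
})

test_that("doubling population and balances leaves availability unchanged", {
  w <- small_world(seed = 8)
  w2 <- w
  w2$population$age_0_4 <- w$population$age_0_4 * 2
  w2$population$age_5_14 <- w$population$age_5_14 * 2
  w2$population$age_15plus <- w$population$age_15plus * 2
  w2$population$total <- w$population$total * 2
  for (col in c("production", "food_demand", "other_demand", "net_trade")) {
    w2$balances[[col]] <- w$balances[[col]] * 2
  }
  s1 <- simulate_market(w, "SSP2")
  s2 <- simulate_market(w2, "SSP2")
  expect_equal(s2$availability$availability, s1$availability$availability,
               tolerance = 1e-9)
  expect_equal(s2$prices$price, s1$prices$price, tolerance = 1e-9)
})

test_that("every solved commodity-year clears the world market", {
  w <- small_world(seed = 3)
  for (sc in c("SSP1", "SSP3")) {
    sim <- simulate_market(w, sc)
    expect_true(all(abs(sim$prices$residual) <=
                      1e-6 * pmax(sim$prices$supply_total, 1e-12)))
    expect_true(all(sim$balances$supply >= 0))
    expect_true(all(sim$balances$food_demand >= 0))
    expect_true(all(sim$availability$availability >= 0))
  }
})

test_that("a higher income path raises prices and consumption, supply fixed", {
  w <- small_world(seed = 6)
  w_hi <- w
  fut <- w_hi$income$year > 2010
  w_hi$income$income[fut] <- w$income$income[fut] * 1.5
  s_lo <- simulate_market(w, "SSP2")
  s_hi <- simulate_market(w_hi, "SSP2")
  p_lo <- s_lo$prices[s_lo$prices$year == 2030, ]
  p_hi <- s_hi$prices[s_hi$prices$year == 2030, ]
  expect_true(all(p_hi$price >= p_lo$price - 1e-9))
  d_lo <- sum(s_lo$balances$food_demand[s_lo$balances$year == 2030])
  d_hi <- sum(s_hi$balances$food_demand[s_hi$balances$year == 2030])
  expect_gte(d_hi, d_lo)
})

test_that("cross-price solver reduces to the separable solution at zero", {
  w <- small_world(seed = 9)
  zero_cross <- matrix(0, 4, 4)
  s0 <- simulate_market(w, "SSP2", years = 2010:2015)
  sx <- simulate_market(w, "SSP2", years = 2010:2015, cross = zero_cross)
  expect_equal(sx$prices$price, s0$prices$price, tolerance = 1e-7)

  # mild substitutability still clears every market
  cr <- matrix(0.05, 4, 4); diag(cr) <- 0
  sy <- simulate_market(w, "SSP2", years = 2010:2012, cross = cr)
  expect_true(all(abs(sy$prices$residual) <=
                    1e-6 * pmax(sy$prices$supply_total, 1e-12)))
})
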