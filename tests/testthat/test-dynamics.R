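test_that("logistic pool update matches hand arithmetic and its equilibrium", {
  expect_equal(pool_update(100, r = 1, K = 100, losses = 0, dt = 0.1), 100)
  expect_equal(pool_update(50, r = 1, K = 100, losses = 0, dt = 0.1), 52.5)
  # productivity scalar scales the growth increment linearly
  g1 <- pool_update(50, 1, 100, productivity_scalar = 1, losses = 0, dt = 0.1) - 50
  g05 <- pool_update(50, 1, 100, productivity_scalar = 0.5, losses = 0, dt = 0.1) - 50
  expect_equal(g05, g1 / 2)
  expect_warning(out <- pool_update(10, 1, 100, losses = 50, dt = 0.1), "floored")
  expect_equal(out, 0)
})

test_that("Baranov mortality partitions deaths between fishing and nature", {
  # unfished limit
  r <- apply_mortality_and_catch(rep(1000, 4), rep(1, 4), M0 = 0.2, M2 = 0.1,
                                 F = 0, age_select = 1L, dt = 1)
  expect_equal(r$catch_numbers, rep(0, 4))
  expect_equal(r$survivors, rep(1000 * exp(-0.3), 4))
  # hand value: (0.2 / 0.5) * 1000 * (1 - exp(-0.5))
  r2 <- apply_mortality_and_catch(1000, 1, M0 = 0.3, M2 = 0, F = 0.2,
                                  age_select = 1L, dt = 1)
  expect_equal(r2$catch_numbers, (0.2 / 0.5) * 1000 * (1 - exp(-0.5)))
  expect_equal(round(r2$catch_numbers, 2), 157.39)
  # knife edge: no catch below the selection age at any F
  r3 <- apply_mortality_and_catch(rep(1000, 5), rep(1, 5), M0 = 0.2, M2 = 0,
                                  F = 3, age_select = 4L, dt = 1)
  expect_equal(r3$catch_numbers[1:3], rep(0, 3))
  expect_true(all(r3$catch_numbers[4:5] > 0))
  expect_error(apply_mortality_and_catch(1, 1, M0 = -0.1, dt = 1), ">= 0")
})

test_that("Baranov accounting identity holds to 1e-10 across random rates", {
  set.seed(42)
  for (i in 1:50) {
    N <- runif(6, 10, 1e6)
    M0 <- runif(1, 0.05, 0.8); M2 <- runif(6, 0, 1.5); F <- runif(1, 0, 2)
    sel <- sample(1:6, 1)
    dt <- sample(c(1 / 12, 0.25, 1), 1)
    r <- apply_mortality_and_catch(N, rep(1, 6), M0, M2, F, sel, dt)
    expect_equal(N - r$survivors, r$deaths, tolerance = 1e-12)
    S <- as.numeric(1:6 >= sel)
    Z <- M0 + M2 + F * S
    expect_lt(max(abs(r$catch_numbers - (F * S / Z) * r$deaths)), 1e-10)
    expect_true(all(r$survivors <= N))
  }
})

test_that("weight relaxes to the ration-scaled reference", {
  expect_equal(update_growth(2, 1, 1, W_ref = 2, dt = 0.5), 2)    # fixed point
  expect_equal(update_growth(1, 1, 1, W_ref = 2, dt = 0.1, kappa = 1), 1.1)
  # sustained half ration converges to half the reference weight
  W <- 2
  for (i in 1:400) W <- update_growth(W, 0.5, 1, W_ref = 2, dt = 0.1)
  expect_equal(W, 1, tolerance = 1e-6)
  # zero demand leaves the ration at 1
  expect_equal(update_growth(1.5, 0, 0, W_ref = 2, dt = 1), 2)
  expect_error(update_growth(1, 2, 1, W_ref = 2, dt = 1), "exceeds demand")
})

test_that("Beverton-Holt steepness normalisation and spawning gate", {
  expect_equal(recruit(1000, S0 = 1000, R0 = 5e5, h = 0.7), 5e5)
  expect_equal(recruit(200, S0 = 1000, R0 = 5e5, h = 0.7), 0.7 * 5e5)
  expect_equal(recruit(0, S0 = 1000, R0 = 5e5, h = 0.7), 0)
  # holds for any valid steepness
  for (h in c(0.25, 0.5, 0.9, 1)) {
    expect_equal(recruit(1000, 1000, 1e6, h), 1e6)
    expect_equal(recruit(200, 1000, 1e6, h), h * 1e6)
  }
  # gate closed beyond the tapered window
  expect_equal(recruit(1000, 1000, 5e5, 0.7, T_spawn = 8.5,
                       spawn_window = c(2, 6, 1)), 0)
  expect_equal(recruit(1000, 1000, 5e5, 0.7, T_spawn = 4,
                       spawn_window = c(2, 6, 1)), 5e5)
  expect_error(recruit(10, 0, 100, 0.7), "S0")
})

test_that("aging shifts cohorts, accumulates the plus group, and admits recruits", {
  out <- advance_year(c(100, 0, 0), c(1, 2, 3), recruits = 0, W_entrant = 1)
  expect_equal(out$N, c(0, 100, 0))
  out <- advance_year(c(0, 70, 30), c(1, 2, 3), recruits = 50, W_entrant = 1)
  expect_equal(out$N, c(50, 0, 100))     # plus group: N3' = N2 + N3
  expect_equal(out$W[1], 1)
  # conservation apart from recruitment inflow
  set.seed(7)
  for (y in c(1, 2, 3)) {
    N <- runif(6, 0, 1000)
    out <- advance_year(N, rep(1, 6), recruits = 123, W_entrant = 1,
                        years_per_age = y)
    expect_equal(sum(out$N), sum(N) + 123)
  }
  # relative-condition carriage: full condition stays exactly on W_ref
  W_ref <- c(1, 2, 4, 8)
  out <- advance_year(c(10, 20, 30, 40), W_ref, recruits = 5, W_entrant = 1,
                      years_per_age = 2, W_ref = W_ref)
  expect_equal(out$W, W_ref)
})

test_that("consumption flows respect availability, saturation, and the prey cap", {
  cfg <- generate_toy_web(web_recipe("toy3", predator_strength = 0))
  st <- ecocap:::init_state(cfg)
  # decoupled predator: no flows from it
  fl <- compute_consumption(st, cfg$diet, T = 7, dt = 1 / 12, config = cfg)
  expect_true(all(fl$Q["predfish", , ] == 0))
  expect_true(all(fl$Q >= 0))
  # proportional allocation: availabilities 0.2 / 0.4 at equal biomass -> 1:2
  ids <- c("pred", "preyA", "preyB")
  gs <- list(
    group_spec("pred", "age_structured_fish", n_ages = 2, M0 = 0.2,
               age_mature = 1, W_ref = c(1, 2), R0 = 1000, Cmax = 2,
               T_opt = 9, T_max = 16, niche = c(-2, 1, 13, 17)),
    group_spec("preyA", "biomass_pool", r_growth = 1, K_cap = 1000),
    group_spec("preyB", "biomass_pool", r_growth = 1, K_cap = 1000))
  av <- array(0, dim = c(3, 2, 3), dimnames = list(ids, NULL, ids))
  av["pred", , "preyA"] <- 0.2
  av["pred", , "preyB"] <- 0.4
  cfg2 <- food_web_config(gs, diet_matrix(av, c(pred = 300)))
  st2 <- ecocap:::init_state(cfg2)
  fl2 <- compute_consumption(st2, cfg2$diet, T = 9, dt = 1 / 12, config = cfg2)
  qa <- sum(fl2$Q[, , "preyA"]); qb <- sum(fl2$Q[, , "preyB"])
  expect_equal(qb / qa, 2)
  # saturation limit: overwhelming prey field drives intake to demand
  st3 <- st2; st3$B_pool[c("preyA", "preyB")] <- 1e12
  fl3 <- compute_consumption(st3, cfg2$diet, T = 9, dt = 1 / 12, config = cfg2)
  expect_equal(sum(fl3$intake), sum(fl3$demand), tolerance = 1e-6)
  # per-prey removal cap with proportional rescaling
  st4 <- st2; st4$B_pool[c("preyA", "preyB")] <- 0.01
  fl4 <- compute_consumption(st4, cfg2$diet, T = 9, dt = 1 / 12, config = cfg2)
  expect_lte(sum(fl4$Q[, , "preyA"]), 0.9 * 0.01 + 1e-12)
  expect_lte(sum(fl4$Q[, , "preyB"]), 0.9 * 0.01 + 1e-12)
  expect_true(all(fl4$intake <= fl4$demand + 1e-12))
})
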