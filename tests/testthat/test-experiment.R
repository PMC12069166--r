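test_that("the F grid spans 0 to 4x the base rate in 13 even multipliers", {
  g <- f_grid(0.23)
  expect_length(g, 13L)
  expect_identical(g[1], 0)
  expect_equal(max(g), 0.92)
  expect_true(all(diff(g) > 0))
  expect_equal(f_grid(0.31)[10], 0.31 * 3)
  expect_true(0.31 %in% round(f_grid(0.31), 10))  # multiplier 1 on the grid
  expect_equal(f_multipliers(), seq(0, 4, length.out = 13))
  expect_error(f_grid(0), "> 0")
})

test_that("step-1 enumeration is |focal| x 13 for any focal set", {
  hist <- hist_regime()
  for (nf in c(1L, 3L, 12L)) {
    cfg <- multi_solo_config(nf)
    s1 <- run_step1(cfg, regime = hist, total_years = 8, burn_in_years = 2)
    expect_identical(s1$n_runs, nf * 13L)
    expect_length(s1$mfmsy, nf)
    expect_named(s1$mfmsy, focal_ids(cfg))
  }
})

test_that("profiled F_MSY matches a dense-grid closed-form argmax", {
  cfg <- solo_config(M0 = 0.2, F_OFL = 0.3, age_select = 2, h = 1)
  prof <- profile_fmsy(cfg, "solo", hist_regime(),
                       total_years = 50, burn_in_years = 20)
  # independent oracle: closed-form equilibrium yield on 1,000 F values
  dense <- seq(0, 4 * 0.3, length.out = 1000)
  yd <- vapply(dense, ypr_equilibrium_catch, 0, config = cfg)
  f_oracle <- dense[which.max(yd)]
  step <- diff(prof$grid$F[1:2])
  expect_lte(abs(prof$F_MSY - f_oracle), step + 1e-9)
  # grid yields agree with the closed form at every F
  yc <- vapply(prof$grid$F, ypr_equilibrium_catch, 0, config = cfg)
  nz <- yc > 0
  expect_lt(max(abs(prof$grid$catch[nz] / yc[nz] - 1)), 0.005)
})

test_that("ties break to the smallest F and boundary argmax is flagged", {
  # collapsed stock: zero abundance means zero catch at every grid F
  g0 <- group_spec("gone", "age_structured_fish", n_ages = 4, M0 = 0.3,
                   F_OFL = 0.2, age_mature = 2, W_ref = c(1, 2, 3, 4),
                   R0 = 1e6, h = 0.8, Cmax = 1, T_opt = 9, T_max = 16,
                   spawn_window = c(0, 12, 1), niche = c(-2, 1, 13, 17),
                   is_focal = TRUE, fished = TRUE, N_init = rep(0, 4))
  cfg <- food_web_config(list(g0))
  prof <- profile_fmsy(cfg, "gone", hist_regime(),
                       total_years = 12, burn_in_years = 4)
  expect_true(all(prof$grid$catch == 0))
  expect_equal(prof$F_MSY, 0)
  # flat weights, selection from age 1: yield increases monotonically in F
  g <- group_spec("flat", "age_structured_fish", n_ages = 4, M0 = 0.6,
                  F_OFL = 0.2, age_mature = 1, age_select = 1,
                  W_ref = rep(1, 4), R0 = 1e6, h = 1, Cmax = 1, T_opt = 9,
                  T_max = 16, spawn_window = c(0, 12, 1),
                  niche = c(-2, 1, 13, 17), is_focal = TRUE, fished = TRUE)
  cfg2 <- food_web_config(list(g))
  prof2 <- profile_fmsy(cfg2, "flat", hist_regime(),
                        total_years = 40, burn_in_years = 15)
  expect_true(prof2$at_boundary)
  expect_equal(prof2$F_MSY, 4 * 0.2)
  expect_error(profile_fmsy(cfg2, "nope", hist_regime()), "unknown group")
})

test_that("scenario policies scale focal F while pinning the key predator", {
  cfg <- multi_solo_config(4L)
  mfmsy <- stats::setNames(c(0.3, 0.4, 0.5, 0.6), focal_ids(cfg))
  pred <- "stock01"
  for (m in c(0, 1, 2.5, 4)) {
    full <- ecocap:::scenario_policy(cfg, mfmsy, m, "full", pred)
    expect_equal(unname(full[names(mfmsy)]), unname(m * mfmsy))
    under <- ecocap:::scenario_policy(cfg, mfmsy, m, "underexploited", pred)
    expect_equal(unname(under[pred]),
                 cfg$groups[[pred]]$F_OFL / 4)     # constant across multipliers
    others <- setdiff(names(mfmsy), pred)
    expect_equal(unname(under[others]), unname(m * mfmsy[others]))
  }
  # quarter-F_OFL pin for an arrowtooth-like F_OFL of 0.23
  cfg2 <- multi_solo_config(1L)
  cfg2$groups$stock01$F_OFL <- 0.23
  under4 <- ecocap:::scenario_policy(cfg2, c(stock01 = 0.5), 4,
                                     "underexploited", "stock01")
  expect_equal(unname(under4["stock01"]), 0.0575)
})

test_that("step 2 enumerates 4 scenarios x 13 multipliers with correct policies", {
  cfg <- multi_solo_config(2L)
  hist <- hist_regime()
  warm <- forcing_series(hist$daily_T + 2.5, label = "warm")
  mfmsy <- stats::setNames(c(0.3, 0.4), focal_ids(cfg))
  s2 <- run_step2(cfg, mfmsy, hist, warm, total_years = 8, burn_in_years = 2,
                  predator_id = "stock01")
  expect_identical(s2$n_runs, 52L)
  expect_identical(sort(s2$scenarios),
                   sort(c("hist_full", "hist_under", "warm_full", "warm_under")))
  expect_equal(nrow(unique(s2$summaries[c("scenario", "multiplier")])), 52L)
  # multiplier 0 under the full policy is the unfished baseline
  m0 <- s2$runs$hist_full[[1]]
  expect_equal(unname(m0$spec$scenario_F[focal_ids(cfg)]), c(0, 0))
})

test_that("scenario spec validates its fields", {
  expect_error(scenario_spec("historical", "full", 5, "arrowtooth"),
               "multiplier")
  s <- scenario_spec("projected", "underexploited", 1, "arrowtooth")
  expect_identical(s$climate, "projected")
})
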