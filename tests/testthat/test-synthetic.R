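test_that("the GOA-like web carries the assessment F_OFL values", {
  cfg <- generate_goa_like_web(web_recipe("goa_like"))
  g <- cfg$groups
  expect_equal(g$arrowtooth$F_OFL, 0.23)
  expect_equal(g$pollock$F_OFL, 0.31)
  expect_equal(g$cod$F_OFL, 0.51)
  expect_equal(g$sablefish$F_OFL, 0.09)
  expect_equal(g$pop$F_OFL, 0.12)
  expect_equal(g$rex_sole$F_OFL, 0.30)
  expect_equal(g$rockfish_slope$F_OFL, 0.06)
  # halibut-like group: base M 0.2, fished, excluded from the cap
  expect_true(is.na(g$halibut$F_OFL))
  expect_equal(g$halibut$M0, 0.2)
  expect_true(g$halibut$is_focal && g$halibut$fished)
  expect_false(g$halibut$counts_toward_cap)
  expect_length(focal_ids(cfg), 12L)
  expect_gte(length(cfg$groups), 20L)
  kinds <- vapply(cfg$groups, function(x) x$kind, "")
  expect_setequal(unique(kinds),
                  c("age_structured_fish", "biomass_pool", "endotherm"))
  # arrowtooth-like predator dominates availability on gadid prey
  adult <- g$arrowtooth$age_mature
  expect_gt(cfg$diet$avail["arrowtooth", adult, "pollock"],
            max(cfg$diet$avail[setdiff(names(g), "arrowtooth"), adult, "pollock"]))
})

test_that("same recipe and seed give byte-identical serialized configs", {
  p1 <- withr::local_tempfile(fileext = ".yml")
  p2 <- withr::local_tempfile(fileext = ".yml")
  write_config(generate_goa_like_web(web_recipe("goa_like", seed = 7L)), p1)
  write_config(generate_goa_like_web(web_recipe("goa_like", seed = 7L)), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("zeroing the predator link decouples the toy web", {
  cfg <- generate_toy_web(web_recipe("toy3", predator_strength = 0))
  zero <- stats::setNames(rep(0, 3), names(cfg$groups))
  res <- run_simulation(cfg, run_spec(60, 30, burn_in_F = zero,
                                      scenario_F = zero,
                                      burn_in_regime = hist_regime()))
  pred <- cfg$groups$predfish
  expected <- ecocap:::unfished_numbers(pred)
  got <- res$final_state$N["predfish", seq_along(expected)]
  expect_lt(max(abs(got / expected - 1)), 0.001)
})

test_that("synthetic forcings pass through the bias-correction pipeline", {
  fr <- generate_forcings(web_recipe("goa_like", warming_delta = 2.5))
  expect_equal(mean(fr$projected$daily_T) - mean(fr$historical$daily_T), 2.5)
  expect_equal(unname(fr$projected$productivity[c("diatoms", "copepods",
                                                  "euphausiids")]),
               rep(0.5, 3))
  # zero warming and zero model bias: projected temperatures equal historical
  fr0 <- generate_forcings(web_recipe("goa_like", warming_delta = 0), bias = 0)
  expect_equal(fr0$projected$daily_T, fr0$historical$daily_T)
  # the alternating interannual offsets cancel exactly in the climatology
  fr1 <- generate_forcings(web_recipe("goa_like"), bias = 1.3)
  expect_equal(fr1$projected$daily_T, fr1$historical$daily_T + 2.5)
})

test_that("the default web is stable over a long unfished run", {
  cfg <- generate_goa_like_web(web_recipe("goa_like"))
  zero <- stats::setNames(rep(0, length(cfg$groups)), names(cfg$groups))
  res <- run_simulation(cfg, run_spec(40, 15, burn_in_F = zero,
                                      scenario_F = zero,
                                      burn_in_regime = hist_regime()))
  ratio <- colMeans(res$biomass[36:40, , drop = FALSE]) / res$biomass[1, ]
  expect_true(all(ratio > 0.5 & ratio < 2))
})

test_that("the cod-like spawning window closes under the warm regime", {
  cfg <- generate_goa_like_web(web_recipe("goa_like"))
  fr <- generate_forcings(web_recipe("goa_like"))
  w <- cfg$groups$cod$spawn_window
  T_hist <- fr$historical$daily_T[cfg$settings$spawn_day]
  T_warm <- fr$projected$daily_T[cfg$settings$spawn_day]
  expect_equal(spawn_gate(T_hist, w), 1)
  expect_equal(spawn_gate(T_warm, w), 0)
})
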