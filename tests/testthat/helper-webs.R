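# shared fixtures, all built in code

hist_regime <- function() forcing_series(ecocap:::historical_daily_T(),
                                         label = "historical")

# single-species configuration with no trophic links; h = 1 makes
# Beverton-Holt recruitment constant at R0 for any positive SSB, so
# equilibrium yield has a closed Baranov yield-per-recruit form
solo_config <- function(id = "solo", M0 = 0.2, F_OFL = 0.3, n_ages = 10L,
                        age_select = 2L, age_mature = 2L, h = 1,
                        Winf = 3, kvb = 0.25, R0 = 1e6,
                        spawn_window = c(0, 12, 1)) {
  g <- group_spec(id, "age_structured_fish", n_ages = n_ages, M0 = M0,
                  F_OFL = F_OFL, age_mature = age_mature,
                  age_select = age_select,
                  W_ref = Winf * (1 - exp(-kvb * seq_len(n_ages)))^3 + 0.01,
                  R0 = R0, h = h, Cmax = 2, T_opt = 9, T_max = 16,
                  spawn_window = spawn_window, niche = c(-2, 1, 13, 17),
                  is_focal = TRUE, fished = TRUE)
  food_web_config(list(g), label = "solo")
}

# closed-form equilibrium Baranov yield (t/yr) for a solo config at
# fishing mortality F with constant recruitment R: start-of-year
# numbers n_1 = R, n_(a+1) = n_a exp(-Z_a), plus-group closure, annual
# catch sum (F S / Z) n (1 - exp(-Z)) W. Independent of the simulator.
ypr_equilibrium_catch <- function(F, config, R = NULL) {
  g <- config$groups[[1]]
  if (is.null(R)) R <- g$R0
  A <- g$n_ages
  S <- as.numeric(seq_len(A) >= g$age_select)
  Z <- g$M0 + F * S
  s <- exp(-Z)
  n <- numeric(A)
  n[1] <- R
  for (a in seq_len(A - 2L)) n[a + 1L] <- n[a] * s[a]
  n[A] <- n[A - 1L] * s[A - 1L] / (1 - s[A])
  sum((F * S / Z) * n * (1 - s) * g$W_ref) / 1000
}

# n decoupled single-species groups, all focal: cheap enumeration web
multi_solo_config <- function(n_focal = 12L) {
  groups <- lapply(seq_len(n_focal), function(i) {
    group_spec(sprintf("stock%02d", i), "age_structured_fish", n_ages = 5L,
               M0 = 0.3, F_OFL = 0.2 + 0.02 * i, age_mature = 2L,
               age_select = 2L,
               W_ref = (1 - exp(-0.3 * (1:5)))^3 + 0.01, R0 = 1e6, h = 0.8,
               Cmax = 2, T_opt = 9, T_max = 16, spawn_window = c(0, 12, 1),
               niche = c(-2, 1, 13, 17), is_focal = TRUE, fished = TRUE)
  })
  food_web_config(groups, label = "multi_solo")
}

# memoised full goa_like experiment shared by the acceptance tests
goa_cache <- new.env(parent = emptyenv())
goa_experiment <- function() {
  if (!is.null(goa_cache$exp)) return(goa_cache$exp)
  recipe <- web_recipe("goa_like")
  forcings <- generate_forcings(recipe)
  config <- generate_goa_like_web(recipe)
  s1 <- run_step1(config, regime = forcings$historical)
  s2 <- run_step2(config, s1$mfmsy, forcings$historical, forcings$projected)
  goa_cache$exp <- list(recipe = recipe, config = config,
                        forcings = forcings, s1 = s1, s2 = s2)
  goa_cache$exp
}
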