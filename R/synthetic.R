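#' Recipe for a synthetic food web and its forcings
#'
#' @param preset `"toy3"` (1 predator fish, 1 prey fish, 1 plankton
#'   pool; analytic equilibria reachable) or `"goa_like"` (26 groups:
#'   12 focal groundfish including an arrowtooth-like key predator and
#'   a warm-sensitive cod-like recruiter, 5 forage groups, 3 plankton
#'   pools, benthos, 5 endotherm top predators).
#' @param seed integer seed recorded in the recipe; generation is
#'   deterministic given the recipe.
#' @param warming_delta uniform warming (degrees C) carried by the
#'   synthetic projection before bias correction (default 2.5).
#' @param predator_strength scale on the arrowtooth-like group's
#'   availability on its gadid prey (default 1; 0 decouples the
#'   top-down link).
#' @return an object of class `web_recipe`.
#' @export
web_recipe <- function(preset = c("goa_like", "toy3"), seed = 1L,
                       warming_delta = 2.5, predator_strength = 1) {
  preset <- match.arg(preset)
  if (warming_delta < 0) stop("warming_delta must be >= 0", call. = FALSE)
  structure(list(preset = preset, seed = as.integer(seed),
                 warming_delta = warming_delta,
                 predator_strength = predator_strength),
            class = "web_recipe")
}

# historical daily temperature climatology: sinusoid, mean 7 degC,
# amplitude 4 degC, coldest in mid-January
historical_daily_T <- function() {
  d <- seq_len(365L)
  7 - 4 * cos(2 * pi * (d - 15) / 365)
}

#' Generate historical and projected (warm) forcing regimes
#'
#' The historical regime is the base sinusoid climatology (mean 7 degC,
#' amplitude 4 degC). The projected regime is produced through the same
#' pipeline applied to real projections: a synthetic multi-year
#' projected daily series (base + `warming_delta` + a model bias +
#' alternating interannual offsets) is delta bias-corrected against the
#' hindcast and historical-run means, collapsed to a daily climatology
#' (the alternating offsets cancel exactly), and the plankton groups'
#' productivity is halved.
#'
#' @param recipe a [web_recipe()].
#' @param plankton_ids plankton group ids whose productivity the warm
#'   regime halves (default the goa_like plankton pools).
#' @param bias synthetic free-running-model bias (degrees C) removed by
#'   the delta correction (default 0.8).
#' @param n_proj_years years in the synthetic projection window
#'   (default 10).
#' @return list with `historical` and `projected` [forcing_series()].
#' @export
generate_forcings <- function(recipe,
                              plankton_ids = c("diatoms", "copepods", "euphausiids"),
                              bias = 0.8, n_proj_years = 10L) {
  base <- historical_daily_T()
  historical <- forcing_series(base, label = "historical")
  offsets <- 0.3 * (-1)^(seq_len(n_proj_years))
  proj <- unlist(lapply(offsets, function(o) base + recipe$warming_delta + bias + o))
  hindcast_mean <- mean(base)
  historical_run_mean <- mean(base) + bias
  corrected <- delta_correct(proj, hindcast_mean, historical_run_mean)
  clim <- build_daily_climatology(corrected)
  projected <- warm_regime(historical, clim, plankton_ids)
  list(historical = historical, projected = projected)
}

#' Generate the three-group toy web
#'
#' A predator fish feeding on a prey fish feeding on a plankton pool.
#' Zeroing the predator-prey availability (via `predator_strength = 0`)
#' decouples the web so each fish group reaches its single-species
#' closed-form unfished equilibrium.
#'
#' @param recipe a [web_recipe()] (preset `"toy3"`).
#' @return a `food_web_config`.
#' @export
generate_toy_web <- function(recipe = web_recipe("toy3")) {
  prey <- group_spec("preyfish", "age_structured_fish", n_ages = 6,
                     M0 = 0.4, F_OFL = 0.3, age_mature = 2, age_select = 2,
                     W_ref = 0.3 * (1 - exp(-0.4 * (1:6)))^3 + 0.01,
                     R0 = 5e7, h = 0.8, Cmax = 3, T_opt = 9, T_max = 16,
                     Qc = 2.5, spawn_window = c(0, 12, 1),
                     niche = c(-2, 1, 13, 17), is_focal = TRUE, fished = TRUE)
  pred <- group_spec("predfish", "age_structured_fish", n_ages = 8,
                     M0 = 0.25, F_OFL = 0.23, age_mature = 3, age_select = 3,
                     W_ref = 4 * (1 - exp(-0.3 * (1:8)))^3 + 0.05,
                     R0 = 2e6, h = 0.7, Cmax = 2.5, T_opt = 8, T_max = 16,
                     Qc = 2.5, spawn_window = c(0, 12, 1),
                     niche = c(-2, 1, 13, 17), is_focal = TRUE, fished = TRUE)
  plank <- group_spec("plankton", "biomass_pool", r_growth = 12, K_cap = 2e5)
  ids <- c("predfish", "preyfish", "plankton")
  A <- 8L
  av <- array(0, dim = c(3, A, 3), dimnames = list(ids, NULL, ids))
  av["preyfish", 1:6, "plankton"] <- 0.5
  av["predfish", 1:8, "preyfish"] <- 0.4 * recipe$predator_strength
  H <- c(predfish = 5e3, preyfish = 2.5e4)
  if (recipe$predator_strength == 0) H <- H["preyfish"]
  food_web_config(list(pred, prey, plank),
                  diet_matrix(av, H),
                  label = sprintf("toy3 (seed %d)", recipe$seed))
}

# life-history table for the goa_like preset. B0 are target unfished
# biomasses (t) at GOA-plausible magnitudes; F_OFL values follow the
# North Pacific assessments for the focal stocks; the halibut-like
# group has no F_OFL (base M = 0.2/yr) and does not count toward the
# cap.
goa_life_history <- function() {
  lh <- function(id, kind, F_OFL, M0, nage, ypa, amat, Winf, kvb, B0, h,
                 Cmax, Topt, Tmax, spawn = c(0, 12, 1), focal = FALSE,
                 cap = focal, fished = focal) {
    list(id = id, kind = kind, F_OFL = F_OFL, M0 = M0, nage = nage,
         ypa = ypa, amat = amat, Winf = Winf, kvb = kvb, B0 = B0, h = h,
         Cmax = Cmax, Topt = Topt, Tmax = Tmax, spawn = spawn,
         focal = focal, cap = cap, fished = fished)
  }
  fish <- "age_structured_fish"
  list(
    lh("arrowtooth", fish, 0.23, 0.20, 10, 2, 3, 3.0, 0.12, 4.8e5, 0.75, 2.5, 8.0, 16.0, focal = TRUE),
    lh("pollock", fish, 0.31, 0.30, 10, 1, 4, 1.2, 0.25, 7.2e5, 0.70, 3.0, 9.0, 15.5, focal = TRUE),
    lh("cod", fish, 0.51, 0.38, 10, 1, 4, 12.0, 0.18, 3.0e5, 0.75, 2.5, 8.0, 15.0,
       spawn = c(2, 6, 1), focal = TRUE),
    lh("sablefish", fish, 0.09, 0.10, 10, 3, 3, 5.5, 0.15, 1.8e5, 0.65, 2.0, 8.0, 17.0, focal = TRUE),
    lh("pop", fish, 0.12, 0.07, 10, 3, 3, 1.5, 0.15, 2.4e5, 0.60, 1.8, 7.0, 16.0, focal = TRUE),
    lh("flathead_sole", fish, 0.25, 0.20, 10, 2, 3, 1.0, 0.20, 1.5e5, 0.75, 2.0, 8.0, 16.0, focal = TRUE),
    lh("rex_sole", fish, 0.30, 0.17, 10, 2, 3, 0.9, 0.20, 9.0e4, 0.75, 2.0, 8.0, 16.0, focal = TRUE),
    lh("deep_flatfish", fish, 0.11, 0.10, 10, 2, 3, 2.0, 0.15, 6.0e4, 0.70, 1.8, 7.0, 16.0, focal = TRUE),
    lh("shallow_flatfish", fish, 0.25, 0.20, 10, 2, 3, 1.2, 0.20, 1.2e5, 0.75, 2.0, 9.0, 16.5, focal = TRUE),
    lh("rockfish_pelagic", fish, 0.11, 0.09, 10, 3, 3, 1.0, 0.12, 6.0e4, 0.65, 1.8, 8.0, 16.0, focal = TRUE),
    lh("rockfish_slope", fish, 0.06, 0.05, 10, 3, 3, 1.2, 0.10, 9.0e4, 0.60, 1.5, 7.0, 16.0, focal = TRUE),
    lh("halibut", fish, NA, 0.20, 10, 3, 3, 40.0, 0.10, 1.5e5, 0.75, 2.0, 8.0, 16.0,
       focal = TRUE, cap = FALSE),
    lh("capelin", fish, NA, 0.70, 4, 1, 2, 0.025, 0.5, 3.0e5, 0.70, 4.0, 8.5, 15.5, fished = TRUE),
    lh("sand_lance", fish, NA, 0.70, 4, 1, 2, 0.020, 0.5, 2.4e5, 0.70, 4.0, 8.5, 15.5, fished = TRUE),
    lh("herring", fish, NA, 0.50, 6, 1, 2, 0.150, 0.4, 1.8e5, 0.70, 3.5, 8.5, 15.5, fished = TRUE),
    lh("eulachon", fish, NA, 0.70, 4, 1, 2, 0.040, 0.5, 9.0e4, 0.70, 4.0, 8.0, 15.5, fished = TRUE),
    lh("slope_forage", fish, NA, 0.60, 4, 1, 2, 0.030, 0.5, 3.6e5, 0.70, 3.5, 7.0, 15.5, fished = TRUE),
    lh("sea_lion", "endotherm", NA, 0.12, 8, 2, 2, 350, 0.35, 1.8e4, 0.75, 15, 8, 16),
    lh("pinniped", "endotherm", NA, 0.12, 8, 2, 2, 90, 0.40, 1.5e4, 0.75, 18, 8, 16),
    lh("dolphin_porpoise", "endotherm", NA, 0.12, 8, 2, 2, 120, 0.40, 1.2e4, 0.75, 20, 8, 16),
    lh("seabird_surface", "endotherm", NA, 0.15, 6, 1, 2, 1.5, 0.8, 2.4e3, 0.75, 80, 8, 16),
    lh("seabird_diving", "endotherm", NA, 0.15, 6, 1, 2, 1.2, 0.8, 2.4e3, 0.75, 80, 8, 16),
    lh("diatoms", "biomass_pool", NA, NA, 1, 1, 1, NA, NA, 3.6e6, NA, NA, NA, NA),
    lh("copepods", "biomass_pool", NA, NA, 1, 1, 1, NA, NA, 2.4e6, NA, NA, NA, NA),
    lh("euphausiids", "biomass_pool", NA, NA, 1, 1, 1, NA, NA, 1.8e6, NA, NA, NA, NA),
    lh("benthos", "biomass_pool", NA, NA, 1, 1, 1, NA, NA, 4.8e6, NA, NA, NA, NA)
  )
}

# pool logistic parameters (r in 1/yr, K = B0 target in t)
goa_pool_params <- function() {
  list(diatoms = c(r = 25), copepods = c(r = 12), euphausiids = c(r = 10),
       benthos = c(r = 2.5))
}

# diet links: pred, prey, juvenile availability (ages < age_mature),
# adult availability. `ps` scales the arrowtooth-like group's
# availability on its gadid prey (top-down control dial).
goa_diet_links <- function(ps = 1) {
  L <- function(pred, prey, juv, adult) list(pred = pred, prey = prey,
                                             juv = juv, adult = adult)
  list(
    L("arrowtooth", "euphausiids", 0.30, 0.05),
    L("arrowtooth", "capelin", 0.30, 0.25),
    L("arrowtooth", "sand_lance", 0.10, 0.10),
    L("arrowtooth", "herring", 0.05, 0.10),
    L("arrowtooth", "eulachon", 0.05, 0.05),
    L("arrowtooth", "slope_forage", 0.10, 0.10),
    L("arrowtooth", "pollock", 0.15 * ps, 0.50 * ps),
    L("arrowtooth", "cod", 0.05 * ps, 0.20 * ps),
    L("arrowtooth", "flathead_sole", 0.00, 0.05),
    L("pollock", "copepods", 0.50, 0.20),
    L("pollock", "euphausiids", 0.30, 0.40),
    L("pollock", "capelin", 0.00, 0.20),
    L("pollock", "eulachon", 0.00, 0.10),
    L("pollock", "slope_forage", 0.00, 0.10),
    L("pollock", "benthos", 0.00, 0.05),
    L("cod", "benthos", 0.40, 0.40),
    L("cod", "pollock", 0.05, 0.20),
    L("cod", "capelin", 0.10, 0.15),
    L("cod", "sand_lance", 0.05, 0.10),
    L("cod", "herring", 0.00, 0.10),
    L("cod", "flathead_sole", 0.00, 0.05),
    L("sablefish", "euphausiids", 0.30, 0.20),
    L("sablefish", "slope_forage", 0.20, 0.30),
    L("sablefish", "eulachon", 0.10, 0.10),
    L("sablefish", "pollock", 0.00, 0.10),
    L("sablefish", "benthos", 0.10, 0.15),
    L("pop", "copepods", 0.40, 0.20),
    L("pop", "euphausiids", 0.40, 0.50),
    L("pop", "slope_forage", 0.00, 0.15),
    L("flathead_sole", "benthos", 0.50, 0.50),
    L("flathead_sole", "euphausiids", 0.20, 0.10),
    L("flathead_sole", "capelin", 0.00, 0.10),
    L("rex_sole", "benthos", 0.60, 0.60),
    L("rex_sole", "euphausiids", 0.20, 0.10),
    L("deep_flatfish", "benthos", 0.60, 0.60),
    L("deep_flatfish", "euphausiids", 0.10, 0.05),
    L("shallow_flatfish", "benthos", 0.60, 0.60),
    L("shallow_flatfish", "sand_lance", 0.00, 0.10),
    L("shallow_flatfish", "capelin", 0.00, 0.05),
    L("rockfish_pelagic", "euphausiids", 0.50, 0.40),
    L("rockfish_pelagic", "copepods", 0.20, 0.10),
    L("rockfish_pelagic", "sand_lance", 0.00, 0.15),
    L("rockfish_pelagic", "capelin", 0.00, 0.10),
    L("rockfish_slope", "euphausiids", 0.50, 0.40),
    L("rockfish_slope", "copepods", 0.20, 0.10),
    L("rockfish_slope", "slope_forage", 0.00, 0.20),
    L("halibut", "benthos", 0.30, 0.20),
    L("halibut", "pollock", 0.05, 0.25),
    L("halibut", "cod", 0.02, 0.10),
    L("halibut", "arrowtooth", 0.00, 0.15),
    L("halibut", "flathead_sole", 0.00, 0.10),
    L("halibut", "capelin", 0.10, 0.05),
    L("halibut", "herring", 0.00, 0.05),
    L("capelin", "copepods", 0.60, 0.60),
    L("capelin", "euphausiids", 0.30, 0.30),
    L("capelin", "diatoms", 0.10, 0.10),
    L("sand_lance", "copepods", 0.60, 0.60),
    L("sand_lance", "euphausiids", 0.30, 0.30),
    L("sand_lance", "diatoms", 0.10, 0.10),
    L("herring", "copepods", 0.50, 0.50),
    L("herring", "euphausiids", 0.40, 0.40),
    L("herring", "diatoms", 0.05, 0.05),
    L("eulachon", "copepods", 0.60, 0.60),
    L("eulachon", "euphausiids", 0.30, 0.30),
    L("slope_forage", "copepods", 0.50, 0.50),
    L("slope_forage", "euphausiids", 0.40, 0.40),
    L("sea_lion", "pollock", 0.05, 0.05),
    L("sea_lion", "cod", 0.25, 0.25),
    L("sea_lion", "arrowtooth", 0.25, 0.25),
    L("sea_lion", "herring", 0.10, 0.10),
    L("sea_lion", "capelin", 0.05, 0.05),
    L("sea_lion", "sablefish", 0.10, 0.10),
    L("sea_lion", "flathead_sole", 0.10, 0.10),
    L("pinniped", "pollock", 0.20, 0.20),
    L("pinniped", "capelin", 0.20, 0.20),
    L("pinniped", "herring", 0.15, 0.15),
    L("pinniped", "sand_lance", 0.15, 0.15),
    L("pinniped", "benthos", 0.10, 0.10),
    L("pinniped", "cod", 0.10, 0.10),
    L("pinniped", "eulachon", 0.05, 0.05),
    L("dolphin_porpoise", "capelin", 0.40, 0.40),
    L("dolphin_porpoise", "sand_lance", 0.20, 0.20),
    L("dolphin_porpoise", "herring", 0.15, 0.15),
    L("dolphin_porpoise", "eulachon", 0.10, 0.10),
    L("dolphin_porpoise", "slope_forage", 0.10, 0.10),
    L("dolphin_porpoise", "pollock", 0.05, 0.05),
    L("seabird_surface", "capelin", 0.35, 0.35),
    L("seabird_surface", "sand_lance", 0.35, 0.35),
    L("seabird_surface", "herring", 0.10, 0.10),
    L("seabird_surface", "eulachon", 0.10, 0.10),
    L("seabird_surface", "slope_forage", 0.05, 0.05),
    L("seabird_diving", "capelin", 0.30, 0.30),
    L("seabird_diving", "sand_lance", 0.30, 0.30),
    L("seabird_diving", "herring", 0.15, 0.15),
    L("seabird_diving", "eulachon", 0.10, 0.10),
    L("seabird_diving", "pollock", 0.05, 0.05)
  )
}

#' Generate the GOA-like synthetic food web
#'
#' Builds a 26-group configuration with the structure the analysis
#' assumes: 12 focal groundfish groups carrying the North Pacific
#' assessment F_OFL values (the halibut-like group has base M = 0.2/yr
#' and does not count toward the cap), 5 forage groups, 3 plankton
#' pools plus benthos, and 5 endotherm top predators. The
#' arrowtooth-like group has dominant availability on pollock-like and
#' cod-like prey (top-down control); the cod-like group's narrow
#' spawning window (2-6 degC, 1 degC taper) closes under the default
#' warm regime.
#'
#' The initial state is placed at the model's own unfished equilibrium:
#' parameters are first anchored analytically (predation mortality M2
#' and consumption rations estimated once at the target biomasses,
#' numbers-at-age set to the exponential structure under M0 + M2,
#' weights to the ration-scaled reference, the Beverton-Holt unfished
#' anchor S0 to the resulting spawning biomass, pools to their
#' logistic balance under the estimated grazing losses), then the web
#' is spun up unfished under historical forcing and the settled state
#' is stored as the initial condition.
#'
#' @param recipe a [web_recipe()] (preset `"goa_like"`).
#' @param spin_up_years length of the internal unfished spin-up
#'   (default 50; 0 skips it).
#' @return a validated `food_web_config`.
#' @export
generate_goa_like_web <- function(recipe = web_recipe("goa_like"),
                                  spin_up_years = 50L) {
  lh <- goa_life_history()
  ids <- vapply(lh, function(x) x$id, "")
  G <- length(ids)
  A <- max(vapply(lh, function(x) x$nage, 1))
  B0 <- stats::setNames(vapply(lh, function(x) x$B0, 0), ids)
  pools <- goa_pool_params()

  av <- array(0, dim = c(G, A, G), dimnames = list(ids, NULL, ids))
  for (ln in goa_diet_links(recipe$predator_strength)) {
    p <- match(ln$pred, ids); q <- match(ln$prey, ids)
    x <- lh[[p]]
    juv <- seq_len(max(x$amat - 1, 0))
    adu <- x$amat:x$nage
    if (length(juv)) av[p, juv, q] <- ln$juv
    av[p, adu, q] <- ln$adult
  }

  # half-saturation: a quarter of the availability-weighted prey field
  # at target biomasses, so the type-II response sits near 80% of
  # demand at the unfished state
  mean_av <- t(vapply(seq_len(G), function(p) {
    na <- lh[[p]]$nage
    colMeans(matrix(av[p, seq_len(na), ], nrow = na, ncol = G))
  }, numeric(G)))
  # mean_av is pred x prey availability averaged over the predator's ages
  field0 <- stats::setNames(as.vector(mean_av %*% B0), ids)
  has_links <- field0 > 0
  H <- 0.25 * field0[has_links]
  rho0 <- stats::setNames(rep(1, G), ids)
  phi0 <- field0[has_links] / H
  rho0[has_links] <- phi0 / (1 + phi0)

  # mean bioenergetic temperature scalar over the historical year
  Tday <- historical_daily_T()
  fbar <- vapply(lh, function(x) {
    if (x$kind != "age_structured_fish") return(1)
    mean(temperature_scalar(Tday, x$Topt, x$Tmax, 2.5))
  }, 0)

  # one-pass predation mortality at target biomasses
  demand0 <- vapply(seq_len(G), function(i) {
    x <- lh[[i]]
    if (x$kind == "biomass_pool") return(0)
    x$Cmax * fbar[i] * B0[i]
  }, 0)
  intake0 <- demand0 * rho0
  alloc <- mean_av * rep(B0, each = G)
  rs <- rowSums(alloc)
  alloc <- alloc / ifelse(rs > 0, rs, 1)
  consumed0 <- as.vector(t(alloc) %*% intake0)
  names(consumed0) <- ids
  M2_0 <- ifelse(B0 > 0, consumed0 / B0, 0)

  groups <- lapply(seq_len(G), function(i) {
    x <- lh[[i]]
    if (x$kind == "biomass_pool") {
      r <- pools[[x$id]]["r"]
      K <- x$B0
      # logistic balance under estimated grazing (upper root), falling
      # back to 0.6 K when grazing exceeds maximum production
      disc <- 1 - 4 * consumed0[x$id] / (r * K)
      Binit <- if (disc > 0) K / 2 * (1 + sqrt(disc)) else 0.6 * K
      return(group_spec(x$id, "biomass_pool", r_growth = unname(r),
                        K_cap = K, B0 = unname(Binit)))
    }
    W_ref <- x$Winf * (1 - exp(-x$kvb * x$ypa * seq_len(x$nage)))^3
    W_ref <- pmax(W_ref, 1e-4 * x$Winf)
    Z0 <- x$M0 + M2_0[x$id]
    g1 <- list(R0 = 1, M0 = Z0, n_ages = x$nage, years_per_age = x$ypa)
    n1 <- unfished_numbers(structure(g1, class = "group_spec"), Z = Z0)
    W_init <- rho0[x$id] * W_ref
    b_pr <- sum(n1 * W_init) / 1000
    R0 <- x$B0 / b_pr
    N_init <- R0 * n1
    matv <- seq_len(x$nage) >= x$amat
    S0 <- sum(N_init[matv] * W_init[matv]) / 1000
    if (x$kind == "endotherm") R0 <- R0 / rho0[x$id]
    group_spec(x$id, x$kind, n_ages = x$nage, years_per_age = x$ypa,
               M0 = x$M0, F_OFL = x$F_OFL, age_mature = x$amat,
               age_select = x$amat, W_ref = W_ref, R0 = R0, h = x$h,
               Cmax = x$Cmax, T_opt = x$Topt, T_max = x$Tmax, Qc = 2.5,
               spawn_window = x$spawn, niche = c(-2, 1, 13, 17),
               is_focal = x$focal, counts_toward_cap = x$cap,
               fished = x$fished, N_init = N_init, W_init = W_init,
               S0 = S0)
  })

  cfg <- food_web_config(groups, diet_matrix(av, H),
                         label = sprintf("goa_like (seed %d)", recipe$seed))
  if (spin_up_years > 0) {
    hist <- forcing_series(historical_daily_T(), label = "historical")
    zero <- stats::setNames(rep(0, G), ids)
    spin <- run_simulation(cfg, run_spec(spin_up_years,
                                         max(1L, spin_up_years %/% 2L),
                                         burn_in_F = zero, scenario_F = zero,
                                         burn_in_regime = hist))
    fs <- spin$final_state
    cfg$groups <- lapply(cfg$groups, function(g) {
      if (g$kind == "biomass_pool") {
        g$B0 <- unname(fs$B_pool[g$id])
      } else {
        g$N_init <- unname(fs$N[g$id, seq_len(g$n_ages)])
        g$W_init <- unname(fs$W[g$id, seq_len(g$n_ages)])
      }
      g
    })
    validate_config(cfg)
  }
  cfg
}

#' Generate a web from a recipe
#'
#' Dispatches on the recipe preset.
#'
#' @param recipe a [web_recipe()].
#' @return a `food_web_config`.
#' @export
generate_web <- function(recipe) {
  switch(recipe$preset,
         toy3 = generate_toy_web(recipe),
         goa_like = generate_goa_like_web(recipe))
}
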