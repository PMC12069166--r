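# Precompute flat, vectorised structures for the stepping engine from a
# validated config. Invalid (beyond n_ages) cells are zero-padded in N
# and carry the last reference weight in W so no NA arithmetic occurs.
sim_build <- function(config) {
  gs <- config$groups
  ids <- names(gs)
  G <- length(ids)
  A <- max(vapply(gs, function(g) g$n_ages, 1L))
  num <- function(f, d = NA_real_) vapply(gs, function(g) {
    v <- g[[f]]
    if (is.null(v) || !length(v)) d else as.numeric(v[1])
  }, 0)
  n_ages <- vapply(gs, function(g) g$n_ages, 1L)
  mask <- outer(n_ages, seq_len(A), `>=`)
  W_ref <- t(vapply(gs, function(g) {
    w <- if (is.null(g$W_ref)) rep(1, g$n_ages) else g$W_ref
    c(w, rep(w[length(w)], A - g$n_ages))
  }, numeric(A)))
  dimnames(W_ref) <- list(ids, NULL)
  sel <- outer(vapply(gs, function(g) g$age_select, 1L), seq_len(A), `<=`) * mask
  mat <- outer(vapply(gs, function(g) g$age_mature, 1L), seq_len(A), `<=`) & mask
  is_pool <- vapply(gs, function(g) g$kind == "biomass_pool", TRUE)
  is_endo <- vapply(gs, function(g) g$kind == "endotherm", TRUE)
  # default S0 is the unfished spawning biomass at the spawn-day
  # census, i.e. the start-of-year closed form discounted by the
  # background mortality elapsed before spawning
  steps <- max(1L, round(1 / config$settings$dt))
  spawn_step <- min(steps, ceiling(config$settings$spawn_day * steps / 365))
  t_spawn <- (spawn_step - 1L) / steps
  S0 <- vapply(gs, function(g) {
    if (g$kind == "biomass_pool") return(NA_real_)
    if (is.finite(g$S0)) g$S0 else unfished_ssb(g) * exp(-g$M0 * t_spawn)
  }, 0)
  av <- config$diet$avail
  pa <- which(apply(av > 0, c(1, 2), any), arr.ind = TRUE)
  keep <- mask[pa] & !is_pool[pa[, 1]]
  pa <- pa[keep, , drop = FALSE]
  AV <- if (nrow(pa)) av[cbind(rep(pa[, 1], G), rep(pa[, 2], G),
                               rep(seq_len(G), each = nrow(pa)))] else numeric(0)
  AV <- matrix(AV, nrow = nrow(pa), ncol = G)
  H_row <- if (nrow(pa)) unname(config$diet$H[ids[pa[, 1]]]) else numeric(0)
  M0 <- num("M0", 0)
  M0[is_pool | !is.finite(M0)] <- 0
  list(ids = ids, G = G, A = A, n_ages = n_ages, mask = mask,
       M0 = M0, Cmax = num("Cmax", 0), T_opt = num("T_opt"),
       T_max = num("T_max"), Qc = num("Qc", 2.5), R0 = num("R0", 0),
       h = num("h", 0.7), F_OFL = num("F_OFL"),
       ypa = vapply(gs, function(g) g$years_per_age, 1L),
       age_select = vapply(gs, function(g) g$age_select, 1L),
       W_ref = W_ref, sel = sel, mat = mat, S0 = S0,
       is_pool = is_pool, is_endo = is_endo,
       is_fish = !is_pool & !is_endo,
       niche = t(vapply(gs, function(g) as.numeric(g$niche), numeric(4))),
       spawn_window = t(vapply(gs, function(g) as.numeric(g$spawn_window), numeric(3))),
       r_growth = num("r_growth"), K_cap = num("K_cap"),
       row_g = unname(pa[, 1]), row_a = unname(pa[, 2]), AV = AV, H_row = H_row,
       predation_cap = config$settings$predation_cap,
       kappa = config$settings$kappa, spawn_day = config$settings$spawn_day)
}

# initial state from config (per-group overrides or analytic defaults)
init_state <- function(config, bld = sim_build(config)) {
  N <- matrix(0, bld$G, bld$A, dimnames = list(bld$ids, NULL))
  W <- bld$W_ref
  B_pool <- stats::setNames(rep(NA_real_, bld$G), bld$ids)
  for (i in seq_len(bld$G)) {
    g <- config$groups[[i]]
    if (g$kind == "biomass_pool") {
      B_pool[i] <- if (is.finite(g$B0)) g$B0 else g$K_cap
      next
    }
    n <- if (!is.null(g$N_init)) g$N_init else unfished_numbers(g)
    N[i, seq_len(g$n_ages)] <- n
    if (!is.null(g$W_init)) W[i, seq_len(g$n_ages)] <- g$W_init
  }
  ecosystem_state(N, W, B_pool, t = 0)
}

#' Calibration fishing policy
#'
#' The calibration (burn-in) fishing mortalities: focal groups with an
#' assessment `F_OFL` are fished at `F_OFL / 4`; other fished groups at
#' `M0 / 4`; everything else is unfished.
#'
#' @param config a `food_web_config`.
#' @return named numeric vector of F (1/yr) per group.
#' @export
calibration_policy <- function(config) {
  vapply(config$groups, function(g) {
    if (!g$fished) return(0)
    if (is.finite(g$F_OFL)) g$F_OFL / 4 else g$M0 / 4
  }, 0)
}

#' Simulation run specification
#'
#' Defines the two-phase protocol: a burn-in under calibration fishing
#' and the historical regime, then an abrupt switch to the scenario
#' fishing policy and regime for the remaining years.
#'
#' @param total_years total simulated years (default 80).
#' @param burn_in_years burn-in years (default 30; must be <
#'   `total_years`).
#' @param burn_in_F named F vector for the burn-in; defaults to
#'   [calibration_policy()] of the config at run time.
#' @param scenario_F named F vector for the scenario phase; defaults to
#'   the burn-in policy (plain continuation).
#' @param burn_in_regime [forcing_series()] for the burn-in (historical).
#' @param scenario_regime [forcing_series()] for the scenario phase;
#'   defaults to the burn-in regime.
#' @param init_jitter sd of optional lognormal jitter applied to the
#'   initial numbers (default 0: fully deterministic).
#' @return an object of class `run_spec`.
#' @export
run_spec <- function(total_years = 80L, burn_in_years = 30L,
                     burn_in_F = NULL, scenario_F = NULL,
                     burn_in_regime, scenario_regime = NULL,
                     init_jitter = 0) {
  if (burn_in_years >= total_years) {
    stop("burn_in_years must be < total_years", call. = FALSE)
  }
  stopifnot(inherits(burn_in_regime, "forcing_series"))
  if (is.null(scenario_regime)) scenario_regime <- burn_in_regime
  structure(list(total_years = as.integer(total_years),
                 burn_in_years = as.integer(burn_in_years),
                 burn_in_F = burn_in_F, scenario_F = scenario_F,
                 burn_in_regime = burn_in_regime,
                 scenario_regime = scenario_regime,
                 init_jitter = init_jitter),
            class = "run_spec")
}

#' Run one food-web simulation
#'
#' Steps the model at `config$settings$dt` (default monthly) through
#' `total_years` years: burn-in under calibration fishing and the
#' historical regime, then the scenario fishing policy and regime.
#' Within each year the engine computes type-II consumption flows,
#' converts them to predation mortality M2, applies Baranov mortality
#' and catch with knife-edge selectivity, updates pools logistically
#' and body mass by ration-dependent relaxation; at each year boundary
#' temperature-gated Beverton-Holt recruitment (fish) or
#' condition-scaled reproduction (endotherms) enters age 1 and classes
#' age with a plus group. The model is deterministic; `seed` only
#' controls the optional initial jitter.
#'
#' @param config a validated `food_web_config`.
#' @param spec a [run_spec()].
#' @param seed integer seed for the optional initialisation jitter.
#' @return an object of class `run_result`: annual series (`catch`,
#'   `ssb`, `biomass`, `recruits` as year x group matrices; `numbers`
#'   as year x group x age; `diet` as year x predator x prey annual
#'   consumed biomass, t), plus the spec echo.
#' @export
run_simulation <- function(config, spec, seed = NULL) {
  validate_config(config)
  bld <- sim_build(config)
  dt <- config$settings$dt
  steps <- max(1L, round(1 / dt))
  dt <- 1 / steps
  st <- init_state(config, bld)
  N <- st$N; W <- st$W; B_pool <- st$B_pool
  if (spec$init_jitter > 0) {
    if (!is.null(seed)) set.seed(seed)
    N <- N * exp(matrix(stats::rnorm(length(N), 0, spec$init_jitter), nrow(N)))
  }
  F_burn <- spec$burn_in_F
  if (is.null(F_burn)) F_burn <- calibration_policy(config)
  F_scen <- spec$scenario_F
  if (is.null(F_scen)) F_scen <- F_burn
  F_burn <- F_burn[bld$ids]; F_scen <- F_scen[bld$ids]
  if (any(is.na(F_burn)) || any(is.na(F_scen)) || any(c(F_burn, F_scen) < 0)) {
    stop("fishing policies must cover every group with F >= 0", call. = FALSE)
  }
  ny <- spec$total_years
  catch <- ssb <- biomass <- recr <-
    matrix(0, ny, bld$G, dimnames = list(NULL, bld$ids))
  numbers <- array(0, dim = c(ny, bld$G, bld$A),
                   dimnames = list(NULL, bld$ids, NULL))
  diet_flow <- array(0, dim = c(ny, bld$G, bld$G),
                     dimnames = list(NULL, bld$ids, bld$ids))
  spawn_step <- min(steps, ceiling(bld$spawn_day / (365 * dt)))
  day_of_step <- pmin(365L, floor((seq_len(steps) - 0.5) * 365 * dt) + 1L)
  pred_groups <- sort(unique(bld$row_g))
  pool_idx <- which(bld$is_pool)
  fish_idx <- which(!bld$is_pool)
  endo_idx <- which(bld$is_endo)
  ypa_fish <- bld$ypa[fish_idx]

  for (year in seq_len(ny)) {
    in_burn <- year <= spec$burn_in_years
    Fv <- if (in_burn) F_burn else F_scen
    regime <- if (in_burn) spec$burn_in_regime else spec$scenario_regime
    prod_s <- rep(1, bld$G)
    if (length(regime$productivity)) {
      m <- match(names(regime$productivity), bld$ids)
      prod_s[m[!is.na(m)]] <- regime$productivity[!is.na(m)]
    }
    Fmat <- Fv * bld$sel
    ssb_spawn <- rep(0, bld$G)
    T_spawn <- regime$daily_T[bld$spawn_day]
    rho_year <- rep(0, bld$G)

    for (s in seq_len(steps)) {
      T <- regime$daily_T[day_of_step[s]]
      if (s == spawn_step) {
        ssb_spawn <- rowSums(bld$mat * N * W) / 1000
      }
      cr <- consumption_rows(bld, N, W, B_pool, T, dt)
      M2 <- rep(0, bld$G)
      hasB <- fish_idx[cr$B[fish_idx] > 0]
      M2[hasB] <- cr$consumed[hasB] / (cr$B[hasB] * dt)
      Z <- bld$M0 + M2 + Fmat
      ed <- exp(-Z * dt)
      surv <- N * ed
      deaths <- N - surv
      cn <- ifelse(Z > 0, Fmat / Z, 0) * deaths
      catch[year, ] <- catch[year, ] + rowSums(cn * W) / 1000
      N <- surv
      if (length(pool_idx)) {
        # sub-step the explicit logistic update so fast pools (r dt
        # near or above 1) stay on the smooth logistic path
        n_sub <- max(1, ceiling(max(bld$r_growth[pool_idx] *
                                      prod_s[pool_idx]) * dt / 0.2))
        for (k in seq_len(n_sub)) {
          B_pool[pool_idx] <- pool_update(B_pool[pool_idx],
                                          bld$r_growth[pool_idx],
                                          bld$K_cap[pool_idx],
                                          productivity_scalar = prod_s[pool_idx],
                                          losses = cr$consumed[pool_idx] / n_sub,
                                          dt = dt / n_sub)
        }
      }
      if (length(cr$row_g)) {
        rho_mat <- matrix(1, bld$G, bld$A)
        rho_mat[cbind(cr$row_g, cr$row_a)] <- cr$rho
        W <- W + bld$kappa * (rho_mat * bld$W_ref - W) * dt
        agg <- rowsum(cr$Q, cr$row_g)
        diet_flow[year, pred_groups, ] <- diet_flow[year, pred_groups, ] + agg
        if (length(endo_idx)) {
          nb <- N[cbind(cr$row_g, cr$row_a)]
          num <- rowsum(cr$rho * nb, cr$row_g)
          den <- rowsum(nb, cr$row_g)
          rg <- as.integer(rownames(num))
          keep <- rg %in% endo_idx & den[, 1] > 0
          rho_year[rg[keep]] <- rho_year[rg[keep]] +
            num[keep, 1] / den[keep, 1]
        }
      } else {
        W <- W + bld$kappa * (bld$W_ref - W) * dt
      }
      if (any(!is.finite(N)) || any(!is.finite(W)) ||
          any(!is.finite(B_pool[pool_idx]))) {
        bad <- bld$ids[unique(c(which(rowSums(!is.finite(N)) > 0),
                                which(rowSums(!is.finite(W)) > 0)))]
        stop(sprintf("simulation diverged in year %d (group %s)", year,
                     paste(bad, collapse = ", ")), call. = FALSE)
      }
    }

    rho_year <- rho_year / steps
    R <- rep(0, bld$G)
    for (i in fish_idx) {
      g <- config$groups[[i]]
      if (bld$is_endo[i]) {
        R[i] <- bld$R0[i] * min(1, max(0, rho_year[i]))
      } else {
        R[i] <- recruit(ssb_spawn[i], bld$S0[i], bld$R0[i], bld$h[i],
                        T_spawn, bld$spawn_window[i, ])
      }
    }
    ssb[year, ] <- ssb_spawn
    biomass[year, ] <- {
      b <- rowSums(N * W) / 1000
      b[pool_idx] <- B_pool[pool_idx]
      b
    }
    recr[year, ] <- R
    numbers[year, , ] <- N
    for (i in fish_idx) {
      na <- bld$n_ages[i]
      adv <- advance_year(N[i, seq_len(na)], W[i, seq_len(na)], R[i],
                          bld$W_ref[i, 1],
                          years_per_age = bld$ypa[i],
                          W_ref = bld$W_ref[i, seq_len(na)])
      N[i, seq_len(na)] <- adv$N
      W[i, seq_len(na)] <- adv$W
    }
  }

  structure(list(years = seq_len(ny), catch = catch, ssb = ssb,
                 biomass = biomass, recruits = recr, numbers = numbers,
                 diet = diet_flow, spec = spec, config_label = config$label,
                 final_state = ecosystem_state(N, W, B_pool, t = ny)),
            class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("<run_result '%s'>  %d years (%d burn-in), %d groups\n",
              x$config_label, length(x$years), x$spec$burn_in_years,
              ncol(x$catch)))
  invisible(x)
}

#' Equilibrium summary over the final five years
#'
#' Means and CVs of annual catch and SSB per group over the last five
#' simulated years, the operational definition of equilibrium used
#' throughout the experiment. CV is `sd/mean`, defined as 0 when the
#' mean is 0.
#'
#' @param result a `run_result` with at least 5 years.
#' @param window number of terminal years to average (default 5).
#' @return data.frame with one row per group: `group`, `mean_catch`,
#'   `cv_catch`, `mean_ssb`, `cv_ssb`, `mean_biomass`.
#' @export
summarize_equilibrium <- function(result, window = 5L) {
  ny <- length(result$years)
  if (ny < window) stop("run shorter than the equilibrium window", call. = FALSE)
  idx <- (ny - window + 1L):ny
  cv <- function(x) if (mean(x) == 0) 0 else stats::sd(x) / mean(x)
  data.frame(group = colnames(result$catch),
             mean_catch = colMeans(result$catch[idx, , drop = FALSE]),
             cv_catch = apply(result$catch[idx, , drop = FALSE], 2, cv),
             mean_ssb = colMeans(result$ssb[idx, , drop = FALSE]),
             cv_ssb = apply(result$ssb[idx, , drop = FALSE], 2, cv),
             mean_biomass = colMeans(result$biomass[idx, , drop = FALSE]),
             row.names = NULL)
}
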