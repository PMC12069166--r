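#' Fishing-mortality grid for profiling
#'
#' 13 evenly spaced F values from 0 to 4 times the base rate (the
#' assessment `F_OFL`, or natural mortality for groups without one):
#' multipliers `0, 1/3, 2/3, ..., 4`. Both endpoints are included, so
#' the grid contains the unfished run and the base rate itself (at
#' multiplier 1).
#'
#' @param F_base base fishing mortality (1/yr, > 0): `F_OFL` where
#'   available, otherwise `M0`.
#' @param n number of grid values (default 13).
#' @return strictly increasing numeric vector of length `n` starting
#'   at 0.
#' @export
f_grid <- function(F_base, n = 13L) {
  if (!is.finite(F_base) || F_base <= 0) {
    stop("profiling base rate must be > 0", call. = FALSE)
  }
  seq(0, 4, length.out = n) * F_base
}

#' Grid multipliers shared by both experiment steps
#'
#' @param n number of multipliers (default 13).
#' @return numeric vector `0, 1/3, ..., 4`.
#' @export
f_multipliers <- function(n = 13L) seq(0, 4, length.out = n)

# base rate used for profiling a group
profile_base <- function(g) if (is.finite(g$F_OFL)) g$F_OFL else g$M0

#' Profile equilibrium yield over F for one focal group
#'
#' Runs one simulation per grid F with the target group fished at that
#' F and every other fished group held at the calibration policy
#' (1/4 F_OFL, or 1/4 M), then selects as F_MSY the grid F with the
#' highest last-five-year mean catch (ties broken toward the smallest
#' F). Depletion at F_MSY is SSB(F_MSY) / SSB(F = 0) from the same
#' grid.
#'
#' @param config a `food_web_config`.
#' @param group focal group id.
#' @param regime historical [forcing_series()] used for both phases.
#' @param total_years,burn_in_years run protocol (defaults 80 / 30).
#' @param grid optional explicit F grid; defaults to
#'   [f_grid()] of the group's base rate.
#' @return an object of class `msy_profile`: `group`, `grid`
#'   (data.frame `F`, `catch`, `ssb`, `cv_catch`), `F_MSY`,
#'   `depletion_at_FMSY`, `at_boundary` flag.
#' @export
profile_fmsy <- function(config, group, regime, total_years = 80L,
                         burn_in_years = 30L, grid = NULL) {
  g <- config$groups[[group]]
  if (is.null(g)) stop("unknown group '", group, "'", call. = FALSE)
  if (!g$is_focal) stop("group '", group, "' is not focal", call. = FALSE)
  if (is.null(grid)) grid <- f_grid(profile_base(g))
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("F grid must be strictly increasing", call. = FALSE)
  }
  calib <- calibration_policy(config)
  rows <- lapply(grid, function(Fv) {
    pol <- calib
    pol[group] <- Fv
    res <- run_simulation(config, run_spec(total_years, burn_in_years,
                                           scenario_F = pol,
                                           burn_in_regime = regime))
    eq <- summarize_equilibrium(res)
    eq[eq$group == group, ]
  })
  eq <- do.call(rbind, rows)
  prof <- data.frame(F = grid, catch = eq$mean_catch, ssb = eq$mean_ssb,
                     cv_catch = eq$cv_catch)
  best <- which.max(prof$catch)            # which.max takes the first tie
  if (all(prof$catch == 0)) best <- 1L
  structure(list(group = group, grid = prof, F_MSY = grid[best],
                 depletion_at_FMSY = if (prof$ssb[1] > 0) {
                   depletion(prof$ssb[best], prof$ssb[1])
                 } else NA_real_,
                 at_boundary = best == length(grid)),
            class = "msy_profile")
}

#' @export
print.msy_profile <- function(x, ...) {
  cat(sprintf("<msy_profile '%s'>  F_MSY = %.4g (catch %.5g t, depletion %.2f)%s\n",
              x$group, x$F_MSY, x$grid$catch[x$grid$F == x$F_MSY],
              x$depletion_at_FMSY,
              if (x$at_boundary) " [argmax at grid boundary]" else ""))
  invisible(x)
}

#' Step 1: per-stock F profiling across all focal groups
#'
#' Profiles each focal group in turn (13 runs each), returning the
#' MF_MSY vector of selected per-stock F_MSY values. With the default
#' 12 focal groups this enumerates 156 runs.
#'
#' @param config a `food_web_config`.
#' @param focal focal group ids (default [focal_ids()] of the config).
#' @param regime historical [forcing_series()].
#' @param total_years,burn_in_years run protocol.
#' @param progress print one line per group as profiling proceeds.
#' @return list with `mfmsy` (named F_MSY vector), `profiles` (list of
#'   `msy_profile`), `n_runs`.
#' @export
run_step1 <- function(config, focal = focal_ids(config), regime,
                      total_years = 80L, burn_in_years = 30L,
                      progress = FALSE) {
  profiles <- lapply(focal, function(id) {
    if (progress) message("profiling ", id)
    profile_fmsy(config, id, regime, total_years, burn_in_years)
  })
  names(profiles) <- focal
  list(mfmsy = vapply(profiles, function(p) p$F_MSY, 0),
       profiles = profiles,
       n_runs = length(focal) * nrow(profiles[[1]]$grid))
}

#' Scenario specification for Step 2
#'
#' One cell of the Step-2 design: climate regime crossed with the
#' key-predator exploitation policy at one MF_MSY multiplier. Under the
#' `underexploited` policy the predator's F stays at the calibration
#' level (1/4 F_OFL) regardless of the multiplier.
#'
#' @param climate `"historical"` or `"projected"`.
#' @param predator_policy `"full"` or `"underexploited"`.
#' @param multiplier MF_MSY multiplier in \[0, 4\].
#' @param predator_id id of the key predator (arrowtooth-like group).
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(climate = c("historical", "projected"),
                          predator_policy = c("full", "underexploited"),
                          multiplier, predator_id) {
  climate <- match.arg(climate)
  predator_policy <- match.arg(predator_policy)
  if (multiplier < 0 || multiplier > 4) {
    stop("multiplier must be in [0, 4]", call. = FALSE)
  }
  structure(list(climate = climate, predator_policy = predator_policy,
                 multiplier = multiplier, predator_id = predator_id),
            class = "scenario_spec")
}

# the four named scenarios of the design
step2_scenarios <- function() {
  list(hist_full = c("historical", "full"),
       hist_under = c("historical", "underexploited"),
       warm_full = c("projected", "full"),
       warm_under = c("projected", "underexploited"))
}

# realized scenario fishing policy for one multiplier
scenario_policy <- function(config, mfmsy, multiplier, predator_policy,
                            predator_id) {
  pol <- calibration_policy(config)
  pol[names(mfmsy)] <- multiplier * mfmsy
  if (predator_policy == "underexploited") {
    g <- config$groups[[predator_id]]
    pol[predator_id] <- profile_base(g) / 4
  }
  pol
}

#' Step 2: multispecies MF_MSY multipliers under four scenarios
#'
#' Crosses the four climate x predator-exploitation scenarios with the
#' 13 MF_MSY multipliers (52 runs by default). Focal groups are fished
#' at `multiplier * F_MSY`; under the underexploited policy the key
#' predator stays at its calibration F; all non-focal fished groups
#' stay at 1/4 M. Projected-climate scenarios use the warm regime
#' (bias-corrected climatology, halved plankton productivity) for the
#' post-burn-in phase; the burn-in is always historical.
#'
#' @param config a `food_web_config`.
#' @param mfmsy named MF_MSY vector from [run_step1()].
#' @param historical,warm the two [forcing_series()] regimes.
#' @param multipliers multiplier grid (default [f_multipliers()]).
#' @param predator_id key predator id (default the arrowtooth-like
#'   group if present, else the first focal id).
#' @param total_years,burn_in_years run protocol.
#' @param progress print one line per scenario.
#' @return list with `runs` (nested: scenario name -> one `run_result`
#'   per multiplier), `summaries` (data.frame over scenario x
#'   multiplier x group of last-5-yr means/CVs), `scenarios`,
#'   `multipliers`, `n_runs`.
#' @export
run_step2 <- function(config, mfmsy, historical, warm,
                      multipliers = f_multipliers(),
                      predator_id = NULL,
                      total_years = 80L, burn_in_years = 30L,
                      progress = FALSE) {
  if (is.null(predator_id)) {
    f <- focal_ids(config)
    predator_id <- if ("arrowtooth" %in% f) "arrowtooth" else f[1]
  }
  scen <- step2_scenarios()
  runs <- list()
  summaries <- list()
  for (sn in names(scen)) {
    if (progress) message("scenario ", sn)
    climate <- scen[[sn]][1]
    policy <- scen[[sn]][2]
    regime <- if (climate == "historical") historical else warm
    runs[[sn]] <- lapply(multipliers, function(m) {
      pol <- scenario_policy(config, mfmsy, m, policy, predator_id)
      run_simulation(config, run_spec(total_years, burn_in_years,
                                      scenario_F = pol,
                                      burn_in_regime = historical,
                                      scenario_regime = regime))
    })
    names(runs[[sn]]) <- format(multipliers, trim = TRUE)
    summaries[[sn]] <- do.call(rbind, lapply(seq_along(multipliers), function(k) {
      eq <- summarize_equilibrium(runs[[sn]][[k]])
      cbind(scenario = sn, multiplier = multipliers[k], eq)
    }))
  }
  list(runs = runs, summaries = do.call(rbind, c(summaries, make.row.names = FALSE)),
       scenarios = names(scen), multipliers = multipliers,
       n_runs = length(scen) * length(multipliers),
       predator_id = predator_id)
}
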