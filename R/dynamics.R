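#' Ecosystem state container
#'
#' Snapshot of the food web at one instant: numbers-at-age and
#' weight-at-age for age-structured groups, biomass for pools.
#'
#' @param N numeric matrix `[group, age]` of abundances (individuals);
#'   rows named by group id; entries beyond a group's `n_ages` are `NA`.
#' @param W numeric matrix `[group, age]` of body masses (kg).
#' @param B_pool named numeric vector of pool biomasses (t); `NA` for
#'   non-pool groups.
#' @param t simulation time (yr, fractional).
#' @return an object of class `ecosystem_state`.
#' @export
ecosystem_state <- function(N, W, B_pool, t = 0) {
  stopifnot(is.matrix(N), is.matrix(W), identical(dim(N), dim(W)))
  if (any(N < 0, na.rm = TRUE) || any(W < 0, na.rm = TRUE) ||
      any(B_pool < 0, na.rm = TRUE)) {
    stop("ecosystem state must be non-negative", call. = FALSE)
  }
  structure(list(N = N, W = W, B_pool = B_pool, t = t),
            class = "ecosystem_state")
}

#' Total biomass per group (t)
#'
#' Age-structured groups: `sum(N * W) / 1000`; pools: `B_pool`.
#'
#' @param state an `ecosystem_state`.
#' @return named numeric vector of biomasses (t).
#' @export
group_biomass <- function(state) {
  b <- rowSums(state$N * state$W, na.rm = TRUE) / 1000
  pool <- !is.na(state$B_pool)
  b[pool] <- state$B_pool[pool]
  b
}

#' Multispecies type-II consumption flows
#'
#' Computes per predator age class the consumption demand
#' `D = Cmax * f(T) * sigma(T) * W * N * dt` (t), the available prey
#' field `phi = sum_p a * B_p / H`, the realised intake
#' `D * phi / (1 + phi)` allocated across prey proportionally to
#' `a * B_p`, and caps total removal from any one prey at
#' `predation_cap` (default 0.9) of its biomass per step with
#' proportional rescaling. Predator age classes with no diet links have
#' zero demand (they are treated as externally fed, so their growth
#' ration is unconstrained).
#'
#' @param state an [ecosystem_state()].
#' @param diet a [diet_matrix()].
#' @param T water temperature (degrees C) for this step.
#' @param dt step length (yr).
#' @param config the `food_web_config` (thermal parameters, settings).
#' @return list of class `consumption_flows` with elements `Q` (3-D
#'   array `[pred, pred_age, prey]`, t consumed this step), `demand`
#'   and `intake` (`[group, age]` matrices, t), and `consumed` (named
#'   per-prey totals, t).
#' @export
compute_consumption <- function(state, diet, T, dt, config) {
  if (any(state$N < 0, na.rm = TRUE) || any(state$B_pool < 0, na.rm = TRUE)) {
    stop("corrupt state: negative biomass", call. = FALSE)
  }
  bld <- sim_build(config)
  rows <- consumption_rows(bld, state$N, state$W, state$B_pool, T, dt)
  G <- length(bld$ids)
  Q <- array(0, dim = c(G, bld$A, G), dimnames = list(bld$ids, NULL, bld$ids))
  if (length(rows$row_g)) {
    Q[cbind(rep(rows$row_g, G), rep(rows$row_a, G),
            rep(seq_len(G), each = length(rows$row_g)))] <- as.vector(rows$Q)
  }
  demand <- intake <- matrix(0, G, bld$A, dimnames = list(bld$ids, NULL))
  demand[cbind(rows$row_g, rows$row_a)] <- rows$demand
  intake[cbind(rows$row_g, rows$row_a)] <- rows$intake
  structure(list(Q = Q, demand = demand, intake = intake,
                 consumed = stats::setNames(rows$consumed, bld$ids)),
            class = "consumption_flows")
}

# core of the functional response, on the flattened predator-age rows of
# a sim_build. N, W are [group, age]; B_pool named vector. Returns row
# vectors plus per-prey totals and the per-row ration rho.
consumption_rows <- function(bld, N, W, B_pool, T, dt) {
  B <- rowSums(N * W, na.rm = TRUE) / 1000
  pool <- bld$is_pool
  B[pool] <- B_pool[pool]
  if (!length(bld$row_g)) {
    return(list(row_g = integer(0), row_a = integer(0), Q = NULL,
                demand = numeric(0), intake = numeric(0),
                consumed = numeric(length(bld$ids)), rho = numeric(0), B = B))
  }
  fT <- rep(1, length(bld$ids))
  ect <- !pool & !bld$is_endo
  fT[ect] <- temperature_scalar(T, bld$T_opt[ect], bld$T_max[ect], bld$Qc[ect])
  sig <- vapply(seq_along(bld$ids), function(i) {
    if (pool[i]) 1 else trapezoid(T, bld$niche[i, 1], bld$niche[i, 2],
                                  bld$niche[i, 3], bld$niche[i, 4])
  }, 0)
  rg <- bld$row_g; ra <- bld$row_a
  demand <- bld$Cmax[rg] * fT[rg] * sig[rg] *
    W[cbind(rg, ra)] * N[cbind(rg, ra)] * dt / 1000
  prey_field <- bld$AV * rep(B, each = length(rg))       # rows x G, t
  tot_field <- rowSums(prey_field)
  phi <- tot_field / bld$H_row
  intake <- demand * phi / (1 + phi)
  share <- prey_field / ifelse(tot_field > 0, tot_field, 1)
  Q <- share * intake                                    # rows x G
  consumed <- colSums(Q)
  cap <- bld$predation_cap * B
  scale <- ifelse(consumed > cap & consumed > 0, cap / consumed, 1)
  if (any(scale < 1)) {
    Q <- Q * rep(scale, each = length(rg))
    intake <- rowSums(Q)
    consumed <- colSums(Q)
  }
  rho <- ifelse(demand > 0, intake / demand, 1)
  list(row_g = rg, row_a = ra, Q = Q, demand = demand, intake = intake,
       consumed = consumed, rho = rho, B = B)
}

#' Logistic biomass-pool update
#'
#' `B' = B + r * s * B * (1 - B/K) * dt - losses`, floored at 0. The
#' productivity scalar `s` is the hook by which warm-regime forcing
#' halves plankton productivity.
#'
#' @param B current biomass (t).
#' @param r intrinsic growth rate (1/yr, > 0).
#' @param K carrying capacity (t, > 0).
#' @param productivity_scalar `s` in (0, 1].
#' @param losses biomass removed this step (t), e.g. by consumption.
#' @param dt step length (yr).
#' @return updated biomass (t), non-negative.
#' @export
pool_update <- function(B, r, K, productivity_scalar = 1, losses = 0, dt) {
  if (any(r <= 0) || any(K <= 0)) stop("pool needs r > 0 and K > 0", call. = FALSE)
  if (any(productivity_scalar <= 0) || any(productivity_scalar > 1)) {
    stop("productivity scalar must be in (0, 1]", call. = FALSE)
  }
  out <- B + r * productivity_scalar * B * (1 - B / K) * dt - losses
  if (any(out < 0)) {
    warning("pool depleted below zero by losses; floored at 0", call. = FALSE)
    out <- pmax(out, 0)
  }
  out
}

#' Baranov mortality and catch for one group
#'
#' Knife-edge selectivity `S(age) = 1` for `age >= age_select`, total
#' mortality `Z = M0 + M2 + F * S`, survivors `N exp(-Z dt)`, catch in
#' numbers `(F S / Z) N (1 - exp(-Z dt))`. `M2` is the instantaneous
#' predation mortality derived from consumption flows.
#'
#' @param N numbers-at-age.
#' @param W weight-at-age (kg).
#' @param M0 background natural mortality (1/yr).
#' @param M2 predation mortality (1/yr); scalar or per-age.
#' @param F fishing mortality (1/yr).
#' @param age_select first fished age class.
#' @param dt step length (yr).
#' @return list with `survivors`, `catch_numbers`, `catch_biomass` (t)
#'   and `deaths` (numbers dying from all causes).
#' @export
apply_mortality_and_catch <- function(N, W, M0, M2 = 0, F = 0, age_select = 1L, dt) {
  if (any(c(M0, M2, F) < 0)) stop("mortality rates must be >= 0", call. = FALSE)
  S <- as.numeric(seq_along(N) >= age_select)
  Z <- M0 + M2 + F * S
  surv <- N * exp(-Z * dt)
  deaths <- N - surv
  cn <- ifelse(Z > 0, (F * S / Z), 0) * deaths
  list(survivors = surv, catch_numbers = cn,
       catch_biomass = sum(cn * W) / 1000, deaths = deaths)
}

#' Consumption-mediated weight dynamics
#'
#' Body mass relaxes toward the ration-scaled reference weight:
#' `W' = W + kappa * (rho * W_ref - W) * dt` with
#' `rho = realized_intake / demand` (1 when demand is 0). Sustained
#' full rations drive `W` to `W_ref`; sustained half rations to
#' `0.5 W_ref`.
#'
#' @param W current weight-at-age (kg).
#' @param realized_intake,demand realised and maximal consumption this
#'   step (same units; `realized_intake <= demand`).
#' @param W_ref reference weight-at-age (kg).
#' @param dt step length (yr).
#' @param kappa relaxation rate (1/yr), default 1.
#' @return updated weight-at-age (kg).
#' @export
update_growth <- function(W, realized_intake, demand, W_ref, dt, kappa = 1) {
  if (any(realized_intake > demand * (1 + 1e-12))) {
    stop("realized intake exceeds demand", call. = FALSE)
  }
  rho <- ifelse(demand > 0, realized_intake / demand, 1)
  W + kappa * (rho * W_ref - W) * dt
}

#' Temperature-gated Beverton-Holt recruitment
#'
#' Beverton-Holt in steepness form,
#' `R = 4 h R0 SSB / (S0 (1 - h) + SSB (5 h - 1))`, multiplied by the
#' trapezoidal spawning-temperature gate [spawn_gate()]. Returns `R0`
#' at `SSB = S0` and `h R0` at `SSB = 0.2 S0` when the gate is open;
#' a closed gate (spawning-season temperature beyond the tapered
#' window) yields complete recruitment failure.
#'
#' @param SSB spawning stock biomass (t).
#' @param S0 unfished spawning biomass (t, > 0).
#' @param R0 unfished recruitment (individuals/yr).
#' @param h steepness in (0.2, 1].
#' @param T_spawn spawning-season temperature (degrees C).
#' @param spawn_window `c(T_lo, T_hi, tau)`.
#' @return recruits (individuals), >= 0.
#' @export
recruit <- function(SSB, S0, R0, h, T_spawn = NULL, spawn_window = NULL) {
  if (S0 <= 0) stop("S0 must be > 0", call. = FALSE)
  if (h <= 0.2 || h > 1) stop("steepness h must be in (0.2, 1]", call. = FALSE)
  r <- 4 * h * R0 * SSB / (S0 * (1 - h) + SSB * (5 * h - 1))
  if (!is.null(T_spawn)) r <- r * spawn_gate(T_spawn, spawn_window)
  pmax(r, 0)
}

#' Annual aging with plus group and recruitment inflow
#'
#' Advances age classes at each year boundary and inserts recruits
#' into age class 1 at reference entrant weight. Annual classes
#' (`years_per_age = 1`) shift wholesale, with the oldest class
#' accumulating as a plus group (`N_A' = N_(A-1) + N_A`). Multi-year
#' classes graduate fractionally: a fraction `1 / years_per_age` of
#' each class advances per year (the exponential residence-time
#' approximation for stage-structured populations), which preserves
#' the class's mean residence time without cohort pulses. Total
#' numbers are conserved apart from the recruitment inflow. Merged
#' classes take the numbers-weighted mean weight.
#'
#' @param N numbers-at-age (one group).
#' @param W weight-at-age (kg).
#' @param recruits recruitment entering age class 1.
#' @param W_entrant entrant body mass (kg), usually `W_ref[1]`.
#' @param years_per_age calendar years per class (>= 1).
#' @param W_ref optional reference weight-at-age. When supplied,
#'   graduating fish carry their relative condition (`W / W_ref`)
#'   into the next class rather than their absolute mass, so at full
#'   ration the weight-at-age schedule is exactly `W_ref` at every
#'   census while food-driven condition anomalies still propagate
#'   through the age structure. Without it, absolute weights are
#'   mixed.
#' @return list with updated `N` and `W`.
#' @export
advance_year <- function(N, W, recruits, W_entrant, years_per_age = 1L,
                         W_ref = NULL) {
  A <- length(N)
  q <- 1 / years_per_age
  x <- if (is.null(W_ref)) W else W / W_ref   # quantity carried through aging
  x_entrant <- if (is.null(W_ref)) W_entrant else 1
  if (A > 1L) {
    stay <- (1 - q) * N
    grad <- q * N
    newN <- stay + c(0, grad[-A])
    newN[A] <- N[A] + grad[A - 1L]          # plus group: nobody graduates out
    xsum <- stay * x + c(0, grad[-A] * x[-A])
    xsum[A] <- N[A] * x[A] + grad[A - 1L] * x[A - 1L]
    x <- ifelse(newN > 0, xsum / newN, x)
    N <- newN
  }
  tot <- N[1L] + recruits
  x[1L] <- if (tot > 0) (N[1L] * x[1L] + recruits * x_entrant) / tot else x_entrant
  N[1L] <- tot
  W <- if (is.null(W_ref)) x else x * W_ref
  list(N = N, W = W)
}
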