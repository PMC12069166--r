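#' Specify one functional group
#'
#' A functional group is either an age-structured population (fish or
#' endotherm top predator) or a biomass pool (plankton, benthos).
#' Age-structured groups carry life history (age classes, natural
#' mortality, maturity/selectivity ages, reference weight-at-age,
#' Beverton-Holt recruitment), bioenergetic thermal parameters, a
#' spawning-temperature window and a thermal-niche trapezoid. Pools
#' carry logistic growth (`r_growth`, `K_cap`).
#'
#' Ages are 1-based class indices; each class spans `years_per_age`
#' calendar years (multi-year classes for longer-lived species), and
#' aging between classes occurs every `years_per_age` years with the
#' oldest class acting as a plus group.
#'
#' @param id short group name (unique within a config).
#' @param kind one of `"age_structured_fish"`, `"biomass_pool"`,
#'   `"endotherm"`.
#' @param n_ages number of age classes (>= 1).
#' @param years_per_age calendar years per age class (>= 1).
#' @param M0 background natural mortality (1/yr); must be > 0 for
#'   age-structured groups.
#' @param F_OFL overfishing-limit fishing mortality (1/yr) or `NA` when
#'   no assessment estimate exists (such groups are fished at 1/4 M at
#'   calibration).
#' @param age_mature first mature age class.
#' @param age_select first fished age class (knife-edge selectivity);
#'   must not exceed `age_mature` so at least one mature class is fully
#'   selected.
#' @param W_ref reference weight-at-age (kg), strictly positive and
#'   non-decreasing, length `n_ages`.
#' @param R0 unfished recruitment (individuals/yr).
#' @param h Beverton-Holt steepness in (0.2, 1].
#' @param Cmax maximum per-mass consumption rate (1/yr).
#' @param T_opt,T_max bioenergetic optimum and upper lethal temperature
#'   (degrees C), `T_opt < T_max`.
#' @param Qc consumption Q10-like coefficient (> 1).
#' @param spawn_window `c(T_lo, T_hi, tau)`: spawning range and linear
#'   taper width (degrees C).
#' @param niche `c(T0, T1, T2, T3)` trapezoid breakpoints (degrees C)
#'   for habitat suitability.
#' @param is_focal whether the group is one of the focal exploited
#'   stocks manipulated in the experiment.
#' @param counts_toward_cap whether its catch counts toward the
#'   ecosystem cap (halibut-like groups are fished but excluded).
#' @param fished whether the group is fished at all (background groups
#'   at 1/4 M; endotherms and pools typically not).
#' @param r_growth,K_cap logistic growth rate (1/yr) and carrying
#'   capacity (t) for `biomass_pool` groups.
#' @param B0 initial pool biomass (t); defaults to `K_cap`.
#' @param N_init optional initial numbers-at-age (length `n_ages`);
#'   defaults to the unfished exponential structure implied by `R0`
#'   and `M0`.
#' @param W_init optional initial weight-at-age (kg); defaults to
#'   `W_ref`.
#' @param S0 unfished spawning biomass (t) anchoring the Beverton-Holt
#'   curve; defaults to the analytic unfished SSB implied by `R0`,
#'   `M0`, maturity and `W_ref`.
#' @return an object of class `group_spec`.
#' @export
group_spec <- function(id, kind = c("age_structured_fish", "biomass_pool", "endotherm"),
                       n_ages = 1L, years_per_age = 1L, M0 = NA_real_,
                       F_OFL = NA_real_, age_mature = 1L, age_select = age_mature,
                       W_ref = NULL, R0 = NA_real_, h = 0.7, Cmax = NA_real_,
                       T_opt = NA_real_, T_max = NA_real_, Qc = 2.5,
                       spawn_window = c(-Inf, Inf, 1), niche = c(-Inf, -Inf, Inf, Inf),
                       is_focal = FALSE, counts_toward_cap = is_focal,
                       fished = FALSE, r_growth = NA_real_, K_cap = NA_real_,
                       B0 = NA_real_, N_init = NULL, W_init = NULL,
                       S0 = NA_real_) {
  kind <- match.arg(kind)
  num <- function(x) if (is.null(x)) NULL else as.numeric(x)
  g <- list(id = id, kind = kind, n_ages = as.integer(n_ages),
            years_per_age = as.integer(years_per_age), M0 = as.numeric(M0),
            F_OFL = as.numeric(F_OFL),
            age_mature = as.integer(age_mature), age_select = as.integer(age_select),
            W_ref = num(W_ref), R0 = as.numeric(R0), h = as.numeric(h),
            Cmax = as.numeric(Cmax), T_opt = as.numeric(T_opt),
            T_max = as.numeric(T_max), Qc = as.numeric(Qc),
            spawn_window = num(spawn_window), niche = num(niche),
            is_focal = isTRUE(is_focal), counts_toward_cap = isTRUE(counts_toward_cap),
            fished = isTRUE(fished), r_growth = as.numeric(r_growth),
            K_cap = as.numeric(K_cap), B0 = as.numeric(B0),
            N_init = num(N_init), W_init = num(W_init), S0 = as.numeric(S0))
  class(g) <- "group_spec"
  validate_group(g)
  g
}

validate_group <- function(g) {
  fail <- function(...) stop("group '", g$id, "': ", ..., call. = FALSE)
  if (!nzchar(g$id)) stop("group id must be non-empty", call. = FALSE)
  if (g$n_ages < 1L) fail("n_ages must be >= 1")
  if (g$years_per_age < 1L) fail("years_per_age must be >= 1")
  if (g$kind == "biomass_pool") {
    if (!is.finite(g$r_growth) || g$r_growth <= 0) fail("pool needs r_growth > 0")
    if (!is.finite(g$K_cap) || g$K_cap <= 0) fail("pool needs K_cap > 0")
    return(invisible(g))
  }
  if (!is.finite(g$M0) || g$M0 <= 0) fail("M0 must be > 0 for age-structured groups")
  if (is.null(g$W_ref) || length(g$W_ref) != g$n_ages) {
    fail("W_ref must have one value per age class")
  }
  if (any(g$W_ref <= 0) || is.unsorted(g$W_ref)) {
    fail("W_ref must be strictly positive and non-decreasing")
  }
  if (!is.finite(g$R0) || g$R0 <= 0) fail("R0 must be > 0")
  if (!is.finite(g$h) || g$h <= 0.2 || g$h > 1) fail("steepness h must be in (0.2, 1]")
  if (g$age_mature < 1L || g$age_mature > g$n_ages) fail("age_mature out of range")
  if (g$age_select < 1L || g$age_select > g$n_ages) fail("age_select out of range")
  if (g$age_select > g$age_mature) {
    fail("age_select must not exceed age_mature (knife-edge selectivity aligned ",
         "with age at first maturity)")
  }
  if (is.finite(g$F_OFL) && g$F_OFL < 0) fail("F_OFL must be >= 0")
  if (g$kind == "age_structured_fish") {
    if (!is.finite(g$Cmax) || g$Cmax < 0) fail("Cmax must be >= 0")
    if (!is.finite(g$T_opt) || !is.finite(g$T_max) || g$T_opt >= g$T_max) {
      fail("need finite T_opt < T_max")
    }
    if (!is.finite(g$Qc) || g$Qc <= 1) fail("Qc must be > 1")
  }
  sw <- g$spawn_window
  if (length(sw) != 3L || sw[1] > sw[2] || sw[3] < 0) {
    fail("spawn_window must be c(T_lo, T_hi, tau) with T_lo <= T_hi, tau >= 0")
  }
  if (length(g$niche) != 4L || is.unsorted(g$niche)) {
    fail("niche must be 4 ordered breakpoints")
  }
  invisible(g)
}

#' Diet availability matrix
#'
#' Availability `a[pred, pred_age, prey]` in \[0, 1\] scales how much of
#' each prey group's biomass is visible to each predator age class, and
#' a shared per-predator half-saturation biomass `H` (t) sets the scale
#' of the type-II functional response. Biomass pools never predate and
#' self-predation within a group is not represented.
#'
#' @param avail 3-D numeric array `[pred, pred_age, prey]` with group
#'   ids as dimnames on margins 1 and 3, or a long data.frame with
#'   columns `pred`, `pred_age`, `prey`, `availability`.
#' @param H named numeric vector of half-saturation prey biomass (t)
#'   per predator group.
#' @param config the `food_web_config` the matrix belongs to (used for
#'   validation when available).
#' @return an object of class `diet_matrix`.
#' @export
diet_matrix <- function(avail, H, config = NULL) {
  if (is.data.frame(avail)) avail <- diet_df_to_array(avail)
  stopifnot(is.array(avail), length(dim(avail)) == 3L)
  if (any(!is.finite(avail)) || any(avail < 0) || any(avail > 1)) {
    stop("diet availabilities must be in [0, 1]", call. = FALSE)
  }
  if (is.null(names(H)) || any(H <= 0)) {
    stop("half-saturation H must be positive and named by predator id",
         call. = FALSE)
  }
  d <- structure(list(avail = avail, H = H), class = "diet_matrix")
  if (!is.null(config)) validate_diet(d, config)
  d
}

validate_diet <- function(diet, config) {
  ids <- names(config$groups)
  dn <- dimnames(diet$avail)
  if (!identical(dn[[1]], ids) || !identical(dn[[3]], ids)) {
    stop("diet matrix margins must match config group ids", call. = FALSE)
  }
  for (id in ids) {
    g <- config$groups[[id]]
    if (g$kind == "biomass_pool" && any(diet$avail[id, , ] > 0)) {
      stop("biomass pool '", id, "' cannot be a predator", call. = FALSE)
    }
    if (any(diet$avail[id, , id] > 0)) {
      stop("self-predation not supported (group '", id, "')", call. = FALSE)
    }
    if (any(diet$avail[id, , ] > 0) && !(id %in% names(diet$H))) {
      stop("predator '", id, "' has diet links but no half-saturation H",
           call. = FALSE)
    }
  }
  invisible(diet)
}

diet_df_to_array <- function(df) {
  need <- c("pred", "pred_age", "prey", "availability")
  if (!all(need %in% names(df))) {
    stop("diet data.frame needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  preds <- sort(unique(c(df$pred, df$prey)))
  a_max <- max(df$pred_age)
  arr <- array(0, dim = c(length(preds), a_max, length(preds)),
               dimnames = list(preds, NULL, preds))
  arr[cbind(match(df$pred, preds), df$pred_age, match(df$prey, preds))] <-
    df$availability
  arr
}

#' Assemble a food-web configuration
#'
#' Bundles the group specifications, the diet matrix and model-level
#' settings into the single validated object consumed by
#' [run_simulation()].
#'
#' @param groups list of [group_spec()] objects.
#' @param diet a [diet_matrix()] covering all groups (may be omitted
#'   for webs without trophic links, in which case an all-zero matrix
#'   is built).
#' @param settings list of model-level settings; recognised entries and
#'   defaults: `dt = 1/12` (yr), `spawn_day = 90` (day of year at which
#'   SSB and the spawning gate are evaluated), `kappa = 1` (1/yr weight
#'   relaxation rate), `predation_cap = 0.9` (max fraction of prey
#'   biomass removable per step), `b35_baseline = "scenario"`
#'   (`"scenario"` or `"historical"`: which unfished run anchors B35%).
#' @param label configuration name.
#' @return an object of class `food_web_config`.
#' @export
food_web_config <- function(groups, diet = NULL, settings = list(), label = "web") {
  ids <- vapply(groups, function(g) g$id, "")
  if (anyDuplicated(ids)) stop("duplicate group ids", call. = FALSE)
  names(groups) <- ids
  defaults <- list(dt = 1 / 12, spawn_day = 90L, kappa = 1,
                   predation_cap = 0.9, b35_baseline = "scenario")
  settings <- utils::modifyList(defaults, settings)
  if (!settings$b35_baseline %in% c("scenario", "historical")) {
    stop("b35_baseline must be 'scenario' or 'historical'", call. = FALSE)
  }
  if (is.null(diet)) {
    a_max <- max(vapply(groups, function(g) g$n_ages, 1L))
    diet <- diet_matrix(array(0, dim = c(length(ids), a_max, length(ids)),
                              dimnames = list(ids, NULL, ids)),
                        H = stats::setNames(1, ids[1]))
  }
  cfg <- structure(list(groups = groups, diet = diet, settings = settings,
                        label = label),
                   class = "food_web_config")
  validate_config(cfg)
  cfg
}

#' Validate a food-web configuration
#'
#' Re-runs all group, diet and settings invariant checks; called by the
#' constructors and after deserialisation.
#'
#' @param config a `food_web_config`.
#' @return the config, invisibly; errors name the offending group/key.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "food_web_config"))
  lapply(config$groups, validate_group)
  validate_diet(config$diet, config)
  if (config$settings$dt <= 0 || config$settings$dt > 1) {
    stop("dt must be in (0, 1] years", call. = FALSE)
  }
  invisible(config)
}

#' @export
print.food_web_config <- function(x, ...) {
  kinds <- table(vapply(x$groups, function(g) g$kind, ""))
  cat(sprintf("<food_web_config '%s'>  %d groups (%s); %d focal\n",
              x$label, length(x$groups),
              paste(sprintf("%s: %d", names(kinds), kinds), collapse = ", "),
              sum(vapply(x$groups, function(g) g$is_focal, TRUE))))
  invisible(x)
}

# ids by predicate
group_ids <- function(config, where = function(g) TRUE) {
  names(config$groups)[vapply(config$groups, where, TRUE)]
}

#' Focal group ids of a configuration
#' @param config a `food_web_config`.
#' @return character vector of ids flagged `is_focal`.
#' @export
focal_ids <- function(config) group_ids(config, function(g) g$is_focal)

# analytic unfished numbers-at-age for one group (plus-group closed
# form), at the start-of-year census right after aging and recruitment.
# Annual survival s = exp(-Z); a fraction q = 1/years_per_age of each
# class graduates per year, so the start-of-year fixed point is
#   n_1 = R0 / (1 - s (1 - q)),  n_(a+1) = q s n_a / (1 - s (1 - q)),
# with plus-group closure n_A = q s n_(A-1) / (1 - s).
# For years_per_age = 1 this reduces to n_a = R0 exp(-Z (a - 1)) and
# n_A = n_(A-1) exp(-Z) / (1 - exp(-Z)).
unfished_numbers <- function(g, Z = g$M0) {
  q <- 1 / g$years_per_age
  s <- exp(-Z)
  A <- g$n_ages
  n <- numeric(A)
  n[1] <- g$R0 / (1 - s * (1 - q))
  if (A > 1L) {
    for (a in seq_len(A - 2L)) n[a + 1L] <- q * s * n[a] / (1 - s * (1 - q))
    n[A] <- q * s * n[A - 1L] / (1 - s)
  }
  n
}

# analytic unfished spawning biomass (t) from R0, M0, maturity, W_ref
unfished_ssb <- function(g, Z = g$M0) {
  n <- unfished_numbers(g, Z)
  mat <- seq_len(g$n_ages) >= g$age_mature
  sum(n[mat] * g$W_ref[mat]) / 1000
}
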