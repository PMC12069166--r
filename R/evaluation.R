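#' Aggregate yield versus the ecosystem cap
#'
#' For each scenario x multiplier cell, sums the last-five-year mean
#' catches of the cap-countable focal groups (groups flagged
#' `counts_toward_cap = FALSE`, e.g. the halibut-like group, are fished
#' but excluded), compares the aggregate with the cap (attained when
#' aggregate >= cap), and counts focal groups whose SSB fell below the
#' B35% overfishing reference point relative to the unfished
#' (multiplier-0) run of the baseline scenario.
#'
#' @param summaries the `summaries` data.frame from [run_step2()] (or
#'   any data.frame with columns `scenario`, `multiplier`, `group`,
#'   `mean_catch`, `mean_ssb`).
#' @param config the `food_web_config` (supplies focal and
#'   cap-countable flags and the B35% baseline setting).
#' @param cap ecosystem cap (t); default 800000.
#' @param threshold B35% fraction of unfished SSB; default 0.35.
#' @param baseline `"scenario"` (unfished run of the same scenario) or
#'   `"historical"` (unfished run of the historical/full scenario);
#'   defaults to `config$settings$b35_baseline`.
#' @return data.frame of class `cap_evaluation`: one row per scenario x
#'   multiplier with `aggregate_yield`, `cap`, `attained`,
#'   `n_below_b35`.
#' @export
evaluate_cap <- function(summaries, config, cap = 8e5, threshold = 0.35,
                         baseline = config$settings$b35_baseline) {
  focal <- focal_ids(config)
  countable <- group_ids(config, function(g) g$is_focal && g$counts_toward_cap)
  missing <- setdiff(focal, unique(summaries$group))
  if (length(missing)) {
    stop("summaries missing focal group(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cells <- unique(summaries[c("scenario", "multiplier")])
  cells <- cells[order(cells$scenario, cells$multiplier), ]
  hist_scen <- if (baseline == "historical") {
    sc <- unique(summaries$scenario)
    if ("hist_full" %in% sc) "hist_full" else sc[1]
  } else NA_character_
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sc <- cells$scenario[i]; m <- cells$multiplier[i]
    sub <- summaries[summaries$scenario == sc & summaries$multiplier == m, ]
    agg <- sum(sub$mean_catch[sub$group %in% countable])
    base_sc <- if (is.na(hist_scen)) sc else hist_scen
    base <- summaries[summaries$scenario == base_sc &
                        summaries$multiplier == 0, ]
    if (!nrow(base)) {
      stop("no multiplier-0 run available for B35% baseline of scenario '",
           sc, "'", call. = FALSE)
    }
    sv <- stats::setNames(sub$mean_ssb, sub$group)[focal]
    uv <- stats::setNames(base$mean_ssb, base$group)[focal]
    data.frame(scenario = sc, multiplier = m, aggregate_yield = agg,
               cap = cap, attained = agg >= cap,
               n_below_b35 = count_below_b35(sv, uv, threshold))
  }))
  class(out) <- c("cap_evaluation", class(out))
  out
}

#' Count stocks below the B35% reference point
#'
#' @param ssb named SSB per group (t) under the evaluated fishing.
#' @param ssb_unfished named SSB per group from the matching unfished
#'   (multiplier-0) run.
#' @param threshold reference fraction of unfished SSB (default 0.35).
#' @return integer count of groups with `ssb < threshold *
#'   ssb_unfished`; groups with zero unfished SSB are excluded with a
#'   warning.
#' @export
count_below_b35 <- function(ssb, ssb_unfished, threshold = 0.35) {
  if (length(ssb) != length(ssb_unfished)) {
    stop("ssb and ssb_unfished must align", call. = FALSE)
  }
  ok <- ssb_unfished > 0
  if (any(!ok)) {
    warning("excluding group(s) with zero unfished SSB: ",
            paste(names(ssb)[!ok], collapse = ", "), call. = FALSE)
  }
  sum(ssb[ok] < threshold * ssb_unfished[ok])
}

#' Depletion: fraction of unfished spawning biomass
#'
#' @param ssb_at_F SSB under fishing (t).
#' @param ssb_unfished SSB of the matching unfished run (t, > 0).
#' @return `ssb_at_F / ssb_unfished` (slightly above 1 is possible via
#'   predation release).
#' @export
depletion <- function(ssb_at_F, ssb_unfished) {
  if (any(ssb_unfished <= 0)) {
    stop("unfished SSB must be > 0 to compute depletion", call. = FALSE)
  }
  ssb_at_F / ssb_unfished
}

#' Indirect food-web effects of groundfish removals
#'
#' For each forage group: its equilibrium biomass and the percentage
#' change in the total biomass of its predators relative to the
#' unfished (multiplier-0) run of the same scenario. For each
#' top-predator group: its equilibrium biomass and the percentage
#' change in the total biomass of its prey. Predator/prey link sets are
#' derived from the diet matrix (availability > 0 at any predator age).
#'
#' @param summaries the `summaries` data.frame from [run_step2()].
#' @param config the `food_web_config`.
#' @param forage_ids character ids of the forage groups to report.
#' @param predator_ids character ids of the piscivorous top predators
#'   to report.
#' @return data.frame: `scenario`, `multiplier`, `group`, `role`
#'   (`"forage"`/`"predator"`), `biomass` (t), `linked_pct_change`
#'   (percent, `NA` when the link set is empty).
#' @export
indirect_effects <- function(summaries, config, forage_ids, predator_ids) {
  av <- config$diet$avail
  ids <- names(config$groups)
  predators_of <- function(p) ids[apply(av[, , p, drop = FALSE] > 0, 1, any)]
  prey_of <- function(p) ids[apply(av[p, , , drop = FALSE] > 0, 3, any)]
  cells <- unique(summaries[c("scenario", "multiplier")])
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    sc <- cells$scenario[i]; m <- cells$multiplier[i]
    sub <- summaries[summaries$scenario == sc & summaries$multiplier == m, ]
    base <- summaries[summaries$scenario == sc & summaries$multiplier == 0, ]
    b <- stats::setNames(sub$mean_biomass, sub$group)
    b0 <- stats::setNames(base$mean_biomass, base$group)
    link_change <- function(linked) {
      if (!length(linked) || sum(b0[linked]) <= 0) return(NA_real_)
      100 * (sum(b[linked]) / sum(b0[linked]) - 1)
    }
    for (f in forage_ids) {
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = sc, multiplier = m, group = f, role = "forage",
        biomass = unname(b[f]), linked_pct_change = link_change(predators_of(f)))
    }
    for (p in predator_ids) {
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = sc, multiplier = m, group = p, role = "predator",
        biomass = unname(b[p]), linked_pct_change = link_change(prey_of(p)))
    }
  }
  do.call(rbind, rows)
}

#' Realised diet composition of a predator
#'
#' Proportions of each prey in the predator's realised consumption
#' (summed flows) over a window of years; proportions sum to 1 over
#' consumed prey, or an empty vector if nothing was consumed.
#'
#' @param result a `run_result` with recorded diet flows.
#' @param predator predator group id.
#' @param years years to aggregate over (default the last 5).
#' @return named numeric vector of prey proportions.
#' @export
realized_diet_composition <- function(result, predator,
                                      years = utils::tail(result$years, 5L)) {
  flows <- result$diet[years, predator, , drop = FALSE]
  tot <- apply(flows, 3, sum)
  s <- sum(tot)
  if (s == 0) return(stats::setNames(numeric(0), character(0)))
  p <- tot / s
  p[p > 0]
}
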