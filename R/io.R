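# known schema keys
group_schema_keys <- c("id", "kind", "n_ages", "years_per_age", "M0", "F_OFL",
                       "age_mature", "age_select", "W_ref", "R0", "h", "Cmax",
                       "T_opt", "T_max", "Qc", "spawn_window", "niche",
                       "is_focal", "counts_toward_cap", "fished", "r_growth",
                       "K_cap", "B0", "N_init", "W_init", "S0")
settings_schema_keys <- c("dt", "spawn_day", "kappa", "predation_cap",
                          "b35_baseline")

# canonical plain-list form of a config (also the serialized schema)
config_to_list <- function(config) {
  groups <- lapply(config$groups, function(g) {
    g <- unclass(g)
    g[!vapply(g, is.null, TRUE)]
  })
  d <- config$diet
  nz <- which(d$avail > 0, arr.ind = TRUE)
  ids <- dimnames(d$avail)[[1]]
  diet_tab <- if (nrow(nz)) {
    o <- order(nz[, 1], nz[, 2], nz[, 3])
    nz <- nz[o, , drop = FALSE]
    list(pred = ids[nz[, 1]], pred_age = unname(nz[, 2]),
         prey = ids[nz[, 3]], availability = unname(d$avail[nz]))
  } else list(pred = character(0), pred_age = integer(0),
              prey = character(0), availability = numeric(0))
  list(label = config$label,
       settings = config$settings[order(names(config$settings))],
       groups = unname(groups),
       diet = list(links = diet_tab, H = as.list(d$H)))
}

#' Write / read a food-web configuration
#'
#' One documented structured-text (YAML) schema holding the group
#' life-history and thermal parameters, the diet availability links
#' (sparse long form) with per-predator half-saturations, and the
#' model settings. `read_config(write_config(x))` reproduces `x`
#' exactly (numbers serialized at full double precision); unknown keys
#' are rejected with their location.
#'
#' @param config a `food_web_config`.
#' @param path file path (conventionally `.yml`).
#' @return `write_config` returns `path` invisibly; `read_config`
#'   returns a validated `food_web_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "food_web_config"))
  yaml::write_yaml(config_to_list(config), path, precision = 20L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  doc <- yaml::read_yaml(path)
  unknown_top <- setdiff(names(doc), c("label", "settings", "groups", "diet"))
  if (length(unknown_top)) {
    stop("unknown top-level key(s) in ", path, ": ",
         paste(unknown_top, collapse = ", "), call. = FALSE)
  }
  bad_set <- setdiff(names(doc$settings), settings_schema_keys)
  if (length(bad_set)) {
    stop("unknown settings key(s): ", paste(bad_set, collapse = ", "),
         call. = FALSE)
  }
  groups <- lapply(doc$groups, function(g) {
    bad <- setdiff(names(g), group_schema_keys)
    if (length(bad)) {
      stop("unknown key(s) in group '", g$id %||% "?", "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    for (f in c("W_ref", "spawn_window", "niche", "N_init", "W_init")) {
      if (!is.null(g[[f]])) g[[f]] <- as.numeric(unlist(g[[f]]))
    }
    do.call(group_spec, g)
  })
  ids <- vapply(groups, function(g) g$id, "")
  A <- max(vapply(groups, function(g) g$n_ages, 1L))
  av <- array(0, dim = c(length(ids), A, length(ids)),
              dimnames = list(ids, NULL, ids))
  lk <- doc$diet$links
  if (length(lk$pred)) {
    pred <- unlist(lk$pred); prey <- unlist(lk$prey)
    bad <- setdiff(c(pred, prey), ids)
    if (length(bad)) {
      stop("diet links reference unknown group(s): ",
           paste(unique(bad), collapse = ", "), call. = FALSE)
    }
    av[cbind(match(pred, ids), unlist(lk$pred_age), match(prey, ids))] <-
      unlist(lk$availability)
  }
  H <- unlist(doc$diet$H)
  food_web_config(groups, diet_matrix(av, H),
                  settings = doc$settings, label = doc$label %||% "web")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stable digest of a configuration
#'
#' Hash of the canonical serialized form; equal for semantically
#' identical configs regardless of in-memory representation details.
#'
#' @param config a `food_web_config`.
#' @return character hash.
#' @export
config_digest <- function(config) rlang::hash(config_to_list(config))

#' Tidy long form of a run result
#'
#' @param result a `run_result`.
#' @return data.frame with columns `year`, `group`, `metric`
#'   (`catch`/`ssb`/`biomass`/`recruits`), `value`.
#' @export
as_tidy_result <- function(result) {
  stopifnot(inherits(result, "run_result"))
  one <- function(m, name) {
    data.frame(year = rep(result$years, ncol(m)),
               group = rep(colnames(m), each = nrow(m)),
               metric = name, value = as.vector(m))
  }
  rbind(one(result$catch, "catch"), one(result$ssb, "ssb"),
        one(result$biomass, "biomass"), one(result$recruits, "recruits"))
}

#' Write a run result as tidy tab-separated files
#'
#' Writes `<stem>.tsv` (year/group/metric/value) and
#' `<stem>_numbers.tsv` (year/group/age/numbers).
#'
#' @param result a `run_result`.
#' @param stem output path stem (no extension).
#' @return the main file path, invisibly.
#' @export
write_run_result <- function(result, stem) {
  main <- paste0(stem, ".tsv")
  utils::write.table(as_tidy_result(result), main, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  num <- result$numbers
  df <- data.frame(year = rep(result$years, times = dim(num)[2] * dim(num)[3]),
                   group = rep(rep(dimnames(num)[[2]], each = dim(num)[1]),
                               times = dim(num)[3]),
                   age = rep(seq_len(dim(num)[3]),
                             each = dim(num)[1] * dim(num)[2]),
                   numbers = as.vector(num))
  utils::write.table(df[df$numbers > 0, ], paste0(stem, "_numbers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(main)
}

#' Write a run manifest
#'
#' Structured-text (YAML) record of a run or experiment: configuration
#' digest, protocol echo, package version, timestamp and the output
#' paths produced.
#'
#' @param config the `food_web_config` used.
#' @param info named list echoing the protocol (years, policies,
#'   multipliers, ...).
#' @param paths character vector of output paths.
#' @param file manifest path.
#' @return `file`, invisibly.
#' @export
write_manifest <- function(config, info, paths, file) {
  yaml::write_yaml(list(config_digest = config_digest(config),
                        config_label = config$label,
                        software = paste0("ecocap ",
                                          as.character(utils::packageVersion("ecocap"))),
                        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                        protocol = info,
                        outputs = as.list(paths)),
                   file)
  invisible(file)
}
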