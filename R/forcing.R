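#' Climate forcing series (one climatological year)
#'
#' A climate regime for the simulator: a 365-value daily temperature
#' climatology looped year after year (so there is no interannual
#' variability by construction), plus per-group plankton productivity
#' scalars.
#'
#' @param daily_T numeric length-365 daily temperatures (degrees C).
#' @param productivity named numeric vector of productivity scalars in
#'   (0, 1\] keyed by group id; groups not named default to 1.
#' @param label regime name (e.g. "historical", "warm").
#' @return an object of class `forcing_series`.
#' @export
forcing_series <- function(daily_T, productivity = numeric(0), label = "historical") {
  if (length(daily_T) != 365L || any(!is.finite(daily_T))) {
    stop("daily_T must be 365 finite values", call. = FALSE)
  }
  if (length(productivity) &&
      (is.null(names(productivity)) || any(productivity <= 0) || any(productivity > 1))) {
    stop("productivity scalars must be named values in (0, 1]", call. = FALSE)
  }
  structure(list(daily_T = as.numeric(daily_T),
                 productivity = productivity,
                 label = label),
            class = "forcing_series")
}

#' @export
print.forcing_series <- function(x, ...) {
  cat(sprintf("<forcing_series '%s'>  T: mean %.2f, range [%.2f, %.2f] degC",
              x$label, mean(x$daily_T), min(x$daily_T), max(x$daily_T)), "\n")
  if (length(x$productivity)) {
    cat("  productivity scalars:",
        paste(sprintf("%s=%.2g", names(x$productivity), x$productivity),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Delta-method bias correction of projected forcing
#'
#' Corrects a projected value for bias in the projecting climate model:
#' `x' = hindcast_mean + (proj_value - historical_mean)`, i.e. the
#' projection's anomaly relative to the free-running historical model
#' mean is added to the reanalysis-driven hindcast mean over the same
#' reference period. Applied elementwise over daily series.
#'
#' @param proj_value projected value(s).
#' @param hindcast_mean mean of the reanalysis-driven hindcast over the
#'   reference period (same units).
#' @param historical_mean mean of the free-running historical run over
#'   the same reference period (same units).
#' @return corrected value(s), same shape as `proj_value`.
#' @examples
#' delta_correct(7, 5, 6) # 6
#' @export
delta_correct <- function(proj_value, hindcast_mean, historical_mean) {
  if (any(!is.finite(proj_value)) || !is.finite(hindcast_mean) ||
      !is.finite(historical_mean)) {
    stop("delta correction requires finite forcing values", call. = FALSE)
  }
  hindcast_mean + (proj_value - historical_mean)
}

#' Daily climatology across years
#'
#' Collapses a multi-year daily series to one climatological year: day
#' `d` of the output is the mean across years of the day-`d` values.
#' Leap days must be removed by the caller.
#'
#' @param multi_year_daily numeric vector of length `n_years * 365`, or
#'   a matrix with 365 columns (one row per year).
#' @return numeric length-365 climatology.
#' @export
build_daily_climatology <- function(multi_year_daily) {
  if (is.matrix(multi_year_daily)) {
    if (ncol(multi_year_daily) != 365L) {
      stop("climatology input matrix must have 365 columns", call. = FALSE)
    }
    m <- multi_year_daily
  } else {
    if (length(multi_year_daily) %% 365L != 0L || !length(multi_year_daily)) {
      stop("daily series length must be a positive multiple of 365", call. = FALSE)
    }
    m <- matrix(multi_year_daily, ncol = 365L, byrow = TRUE)
  }
  if (any(!is.finite(m))) stop("non-finite values in daily series", call. = FALSE)
  colMeans(m)
}

#' Tile a climatology into a multi-year daily series
#'
#' @param climatology numeric length-365 values.
#' @param n_years number of years to tile (>= 1).
#' @return numeric vector of length `n_years * 365` with exact period
#'   365 (zero interannual variance of any same-day statistic).
#' @export
loop_forcing <- function(climatology, n_years) {
  if (length(climatology) != 365L) stop("climatology must have 365 values", call. = FALSE)
  n_years <- as.integer(n_years)
  if (is.na(n_years) || n_years < 1L) stop("n_years must be >= 1", call. = FALSE)
  rep(as.numeric(climatology), times = n_years)
}

#' Build a warm climate regime from a corrected climatology
#'
#' Attaches the bias-corrected projected climatology to a new regime and
#' halves the productivity of the named plankton groups (productivity
#' scalar 0.5), leaving all other groups at 1.
#'
#' @param base baseline `forcing_series` (its non-plankton scalars are
#'   retained).
#' @param corrected_climatology length-365 delta-corrected projected
#'   daily temperatures.
#' @param plankton_ids character ids of the plankton groups whose
#'   productivity is halved.
#' @param config optional `food_web_config`; when given, `plankton_ids`
#'   are checked against its group ids.
#' @return a `forcing_series` labelled "warm".
#' @export
warm_regime <- function(base, corrected_climatology, plankton_ids, config = NULL) {
  stopifnot(inherits(base, "forcing_series"))
  if (!is.null(config)) {
    unknown <- setdiff(plankton_ids, names(config$groups))
    if (length(unknown)) {
      stop("unknown plankton group id(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  prod <- base$productivity
  prod <- prod[setdiff(names(prod), plankton_ids)]
  if (length(plankton_ids)) {
    prod <- c(prod, stats::setNames(rep(0.5, length(plankton_ids)), plankton_ids))
  }
  forcing_series(corrected_climatology, productivity = prod, label = "warm")
}

# productivity scalar for one group under a regime (default 1)
productivity_scalar <- function(regime, id) {
  s <- regime$productivity[id]
  if (is.na(s)) 1 else unname(s)
}

#' Write / read a forcing series as a two-column table
#'
#' Plain-text representation: tab-separated `day`, `temperature`
#' columns, with the label and any productivity scalars carried in
#' `#`-comment header lines.
#'
#' @param x a `forcing_series`.
#' @param path file path.
#' @return `write_forcing` returns `path` invisibly; `read_forcing`
#'   returns a `forcing_series`.
#' @export
write_forcing <- function(x, path) {
  stopifnot(inherits(x, "forcing_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# label: %s", x$label), con)
  if (length(x$productivity)) {
    writeLines(sprintf("# productivity: %s",
                       paste(sprintf("%s=%s", names(x$productivity),
                                     format(x$productivity, digits = 17)),
                             collapse = ",")), con)
  }
  writeLines("day\ttemperature", con)
  writeLines(sprintf("%d\t%s", seq_len(365L), format(x$daily_T, digits = 17)), con)
  invisible(path)
}

#' @rdname write_forcing
#' @export
read_forcing <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  label <- sub("^# label: ", "", grep("^# label: ", hdr, value = TRUE))
  if (!length(label)) label <- "unnamed"
  prod <- numeric(0)
  pl <- grep("^# productivity: ", hdr, value = TRUE)
  if (length(pl)) {
    kv <- strsplit(strsplit(sub("^# productivity: ", "", pl), ",")[[1]], "=")
    prod <- stats::setNames(vapply(kv, function(p) as.numeric(p[2]), 0),
                            vapply(kv, `[`, "", 1))
  }
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                           sep = "\t")
  forcing_series(tab$temperature[order(tab$day)], productivity = prod,
                 label = label)
}
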