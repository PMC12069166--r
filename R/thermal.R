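#' Unimodal bioenergetic temperature scaling of consumption
#'
#' Scales maximum consumption by a unimodal response of the
#' Kitchell/Thornton–Lessem family: rising from cold temperatures to 1 at
#' the thermal optimum `T_opt`, then falling to 0 at the upper lethal
#' temperature `T_max`. With `V = (T_max - T) / (T_max - T_opt)`,
#' `Z = log(Qc) (T_max - T_opt)`, `Y = log(Qc) (T_max - T_opt + 2)` and
#' `X = Z^2 (1 + sqrt(1 + 40/Y))^2 / 400`, the scalar is
#' `V^X exp(X (1 - V))`, and 0 for `T >= T_max`.
#'
#' Endotherm groups bypass this response in the simulator (their
#' consumption is not a direct function of water temperature).
#'
#' @param T water temperature (degrees C); vectorised.
#' @param T_opt thermal optimum (degrees C), where the scalar equals 1.
#' @param T_max upper lethal temperature (degrees C); must exceed `T_opt`.
#' @param Qc Q10-like rate coefficient (unitless, > 1) controlling the
#'   steepness of the ascending limb.
#' @param group optional group id used in error messages.
#' @return numeric vector of fractions in \[0, 1\].
#' @examples
#' temperature_scalar(10, T_opt = 10, T_max = 15, Qc = 2.5) # 1
#' temperature_scalar(15, T_opt = 10, T_max = 15, Qc = 2.5) # 0
#' @export
temperature_scalar <- function(T, T_opt, T_max, Qc, group = NULL) {
  if (any(!is.finite(T_opt)) || any(!is.finite(T_max)) || any(T_opt >= T_max)) {
    stop("invalid thermal parameters (need T_opt < T_max)",
         if (!is.null(group)) paste0(" for group '", group, "'"), call. = FALSE)
  }
  if (any(!is.finite(Qc)) || any(Qc <= 1)) {
    stop("invalid thermal parameters (need Qc > 1)",
         if (!is.null(group)) paste0(" for group '", group, "'"), call. = FALSE)
  }
  V <- (T_max - T) / (T_max - T_opt)
  Z <- log(Qc) * (T_max - T_opt)
  Y <- log(Qc) * (T_max - T_opt + 2)
  X <- Z^2 * (1 + sqrt(1 + 40 / Y))^2 / 400
  out <- V^X * exp(X * (1 - V))
  out[T >= T_max] <- 0
  pmin(pmax(out, 0), 1)
}

#' Trapezoidal habitat (thermal niche) suitability
#'
#' A 0-D stand-in for thermal-niche restriction of spatial distribution:
#' a trapezoid over temperature that multiplies foraging exposure. Zero
#' outside `[T0, T3]`, one on the plateau `[T1, T2]`, linear on the
#' shoulders.
#'
#' @param T temperature (degrees C); vectorised.
#' @param niche numeric length-4 breakpoints `c(T0, T1, T2, T3)`,
#'   non-decreasing.
#' @param group optional group id used in error messages.
#' @return numeric vector of fractions in \[0, 1\].
#' @export
habitat_suitability <- function(T, niche, group = NULL) {
  if (length(niche) != 4L || any(!is.finite(niche)) || is.unsorted(niche)) {
    stop("niche breakpoints must be 4 ordered finite values",
         if (!is.null(group)) paste0(" for group '", group, "'"), call. = FALSE)
  }
  trapezoid(T, niche[1], niche[2], niche[3], niche[4])
}

#' Trapezoidal spawning-temperature gate
#'
#' Recruitment gate capturing stenothermic reproduction: 1 inside the
#' spawning window `[T_lo, T_hi]`, tapering linearly to 0 over width
#' `tau` on each side (a hard gate when `tau = 0`).
#'
#' @param T spawning-season temperature (degrees C); vectorised.
#' @param window numeric `c(T_lo, T_hi, tau)` with `T_lo <= T_hi`,
#'   `tau >= 0`.
#' @return numeric vector of fractions in \[0, 1\].
#' @export
spawn_gate <- function(T, window) {
  if (length(window) != 3L || window[1] > window[2] || window[3] < 0) {
    stop("spawn window must be c(T_lo, T_hi, tau) with T_lo <= T_hi, tau >= 0",
         call. = FALSE)
  }
  trapezoid(T, window[1] - window[3], window[1], window[2], window[2] + window[3])
}

# piecewise-linear trapezoid; handles zero-width shoulders (step edges)
trapezoid <- function(T, a, b, c, d) {
  out <- numeric(length(T))
  out[T >= b & T <= c] <- 1
  lo <- T > a & T < b
  if (any(lo)) out[lo] <- (T[lo] - a) / (b - a)
  hi <- T > c & T < d
  if (any(hi)) out[hi] <- (d - T[hi]) / (d - c)
  out
}
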