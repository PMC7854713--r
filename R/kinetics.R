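#' @include AllClasses.R
NULL

#' First-order decay curve
#'
#' Evaluates `C_t = C_0 * exp(-k t)`, the first-order exponential decay model
#' for environmental nucleic-acid concentrations.
#'
#' @param c0 Initial concentration (copies/mL, >= 0).
#' @param k Decay constant magnitude (per hour, >= 0).
#' @param t Time in hours (>= 0); vectorised.
#' @return Concentration at `t`, copies/mL.
#' @examples
#' decayCurve(100, log(2), 1)  # 50
#' @export
decayCurve <- function(c0, k, t) {
  if (any(c0 < 0)) stop("'c0' must be >= 0")
  if (any(k < 0)) stop("'k' must be >= 0 (stored as magnitude)")
  if (any(t < 0)) stop("'t' must be >= 0")
  c0 * exp(-k * t)
}

#' Half-life of first-order decay
#'
#' `t_1/2 = ln(2) / k`: the time over which a concentration halves under
#' `C_t = C_0 exp(-k t)`. Strictly decreasing in `k`.
#'
#' @param k Decay constant (per hour, > 0); vectorised.
#' @return Half-life in hours.
#' @examples
#' halfLife(0.0378)  # ~18.34 h
#' @export
halfLife <- function(k) {
  if (any(is.na(k)) || any(k <= 0))
    stop("'k' must be > 0 for a finite half-life")
  log(2) / k
}

#' Confidence interval for the half-life
#'
#' Inverts a Wald interval for the decay constant into half-life bounds:
#' with `k_lower = k - z se` and `k_upper = k + z se`, the interval is
#' `(ln(2)/k_upper, ln(2)/k_lower)`, lower bound first. The default
#' `z = 1.959964` is the exact Normal 97.5% quantile; pass
#' `z = qt(0.975, df)` for a t-based interval when the decay constant comes
#' from a small-sample fit.
#'
#' @param k Decay constant (per hour, > 0).
#' @param se Standard error of `k` (per hour, >= 0).
#' @param z Quantile multiplier, default 1.959964 (95% Normal).
#' @return Numeric length-2 vector `(lower, upper)` in hours; brackets
#'   `halfLife(k)` for any `se > 0` and degenerates to it at `se = 0`.
#' @examples
#' halfLifeInterval(0.0378, 0.0025)  # c(16.23, 21.07) to 2 decimals
#' @export
halfLifeInterval <- function(k, se, z = 1.959964) {
  stopifnot(length(k) == 1L, length(se) == 1L, length(z) == 1L)
  if (is.na(k) || k <= 0) stop("'k' must be > 0")
  if (is.na(se) || se < 0) stop("'se' must be >= 0")
  if (k - z * se <= 0)
    stop("interval for k crosses 0; a Wald inversion is invalid here - ",
         "use a profile-likelihood or bootstrap interval instead")
  c(log(2) / (k + z * se), log(2) / (k - z * se))
}
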