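# Closed-form kinetic model of imino-proton exchange, plus a numerical
# two-pool exchange oracle used to validate the closed form.

#' Relaxation rates for the transfer model
#'
#' Bundles the apparent longitudinal relaxation rate of the imino proton
#' (`R1a`, measured by selective inversion recovery, which already contains
#' the exchange contribution) and the longitudinal relaxation rate of water
#' (`R1w`, measured by saturation recovery), each optionally with a standard
#' error.
#'
#' @param R1a apparent imino-proton longitudinal relaxation rate, s^-1.
#' @param R1w water longitudinal relaxation rate, s^-1.
#' @param R1a_se,R1w_se standard errors, s^-1 (`NA` if unknown).
#' @return An object of class `"relaxation_rates"`.
#' @export
relaxation_rates <- function(R1a, R1w, R1a_se = NA_real_, R1w_se = NA_real_) {
  if (!is.finite(R1a) || !is.finite(R1w) || R1a <= 0 || R1w <= 0)
    stop("R1a and R1w must be finite and > 0", call. = FALSE)
  structure(list(R1a = R1a, R1w = R1w, R1a_se = R1a_se, R1w_se = R1w_se),
            class = "relaxation_rates")
}

#' @export
print.relaxation_rates <- function(x, ...) {
  cat(sprintf("Relaxation rates: R1a = %.4g s^-1", x$R1a))
  if (is.finite(x$R1a_se)) cat(sprintf(" (+/- %.2g)", x$R1a_se))
  cat(sprintf(", R1w = %.4g s^-1", x$R1w))
  if (is.finite(x$R1w_se)) cat(sprintf(" (+/- %.2g)", x$R1w_se))
  cat("\n")
  invisible(x)
}

#' Water magnetization transfer intensity ratio
#'
#' Relative imino-proton intensity I(t)/I0 after selective inversion of the
#' water magnetization, as a function of the recovery delay. The imino signal
#' is attenuated by exchange with the inverted water pool:
#' \deqn{I(t)/I_0 = 1 - 2\,\frac{k_{ex}}{R_{1w}-R_{1a}}
#'       \left(e^{-R_{1a}t} - e^{-R_{1w}t}\right)}
#' When \eqn{|R_{1w}-R_{1a}|} falls below `tol` the degenerate limit
#' \eqn{1 - 2 k_{ex} t e^{-R_{1a}t}} is used instead.
#'
#' @param t delay time(s), s; vectorized.
#' @param k_ex overall imino-proton exchange rate, s^-1.
#' @param rates a [relaxation_rates] object.
#' @param inversion_efficiency fraction of the water magnetization actually
#'   inverted; 1 corresponds to the ideal factor 2.
#' @param tol rate-difference tolerance (s^-1) for switching to the
#'   degenerate-denominator limit.
#' @return Dimensionless intensity ratio(s), same length as `t`.
#' @export
intensity_ratio <- function(t, k_ex, rates, inversion_efficiency = 1,
                            tol = 1e-9) {
  stopifnot(inherits(rates, "relaxation_rates"))
  if (any(!is.finite(t)) || any(t < 0))
    stop("delay times must be finite and >= 0", call. = FALSE)
  if (!is.finite(k_ex) || k_ex < 0)
    stop("k_ex must be finite and >= 0", call. = FALSE)
  R1a <- rates$R1a
  R1w <- rates$R1w
  amp <- 2 * inversion_efficiency * k_ex
  if (abs(R1w - R1a) < tol) {
    1 - amp * t * exp(-R1a * t)
  } else {
    # expm1 form of (exp(-R1a t) - exp(-R1w t))/(R1w - R1a): stable under
    # cancellation when the two rates are nearly equal
    d <- R1w - R1a
    1 - amp * exp(-R1a * t) * (-expm1(-d * t)) / d
  }
}

#' Two-pool exchange oracle (numerical)
#'
#' Integrates the coupled longitudinal magnetization equations for a dilute
#' imino-proton pool exchanging with a large water pool, after inversion of
#' the water magnetization. With normalized per-proton magnetizations
#' \eqn{m_a} (imino) and \eqn{m_w} (water):
#' \deqn{dm_a/dt = -R_{1a}^{int}(m_a - 1) - k_{ex}(m_a - m_w)}
#' \deqn{dm_w/dt = -R_{1w}(m_w - 1) - (k_{ex}/N)(m_w - m_a)}
#' where \eqn{N} is the water-to-imino population ratio; back-exchange is
#' scaled by \eqn{1/N} so detailed balance holds. In the large-\eqn{N} limit
#' the imino trajectory equals the closed form of [intensity_ratio] with
#' apparent \eqn{R_{1a} = R_{1a}^{int} + k_{ex}}.
#'
#' @param t_grid delay times at which to report the solution, s.
#' @param k_ex imino-to-water exchange rate, s^-1.
#' @param R1a_intrinsic intrinsic (exchange-free) imino relaxation rate, s^-1.
#' @param R1w water relaxation rate, s^-1.
#' @param pool_ratio water-to-imino proton population ratio (must be >> 1).
#' @param inversion_efficiency fraction of water magnetization inverted.
#' @return A data frame with columns `time`, `imino`, `water`.
#' @export
mcconnell_two_pool <- function(t_grid, k_ex, R1a_intrinsic, R1w,
                               pool_ratio = 1e6, inversion_efficiency = 1) {
  pars <- c(k_ex, R1a_intrinsic, R1w, pool_ratio, inversion_efficiency)
  if (any(!is.finite(pars)))
    stop("all parameters must be finite", call. = FALSE)
  if (any(!is.finite(t_grid)) || any(t_grid < 0))
    stop("delay times must be finite and >= 0", call. = FALSE)
  if (pool_ratio <= 1)
    stop("pool_ratio must exceed 1 (dilute solute)", call. = FALSE)
  times <- sort(unique(c(0, t_grid)))
  deriv <- function(t, y, p) {
    ma <- y[1]; mw <- y[2]
    list(c(
      -R1a_intrinsic * (ma - 1) - k_ex * (ma - mw),
      -R1w * (mw - 1) - (k_ex / pool_ratio) * (mw - ma)
    ))
  }
  y0 <- c(ma = 1, mw = 1 - 2 * inversion_efficiency)
  sol <- deSolve::lsoda(y0, times, deriv, parms = NULL,
                        rtol = 1e-11, atol = 1e-12)
  sol <- as.data.frame(sol)
  idx <- match(t_grid, sol$time)
  data.frame(time = t_grid, imino = sol$ma[idx], water = sol$mw[idx])
}

#' Overall imino-proton exchange rate from two-state kinetics
#'
#' The observed exchange rate for a base pair that opens at `k_open`, closes
#' at `k_close` and exchanges from the open state at `k_ex_open`:
#' \deqn{k_{ex} = \frac{k_{open}\,k_{ex,open}}{k_{close}+k_{ex,open}}}
#' Since the factor multiplying `k_open` never exceeds 1, the result is always
#' bounded above by `k_open`; in the EX1 limit (`k_ex_open >> k_close`) it
#' equals `k_open`.
#'
#' @param k_open,k_close base-pair opening and closing rates, s^-1.
#' @param k_ex_open open-state exchange rate, s^-1.
#' @return Overall exchange rate k_ex, s^-1.
#' @export
overall_exchange_rate <- function(k_open, k_close, k_ex_open) {
  if (any(c(k_open, k_close, k_ex_open) < 0) ||
      any(!is.finite(c(k_open, k_close))) || any(k_ex_open < 0))
    stop("all rates must be >= 0", call. = FALSE)
  denom <- k_close + k_ex_open
  if (any(denom <= 0))
    stop("k_close + k_ex_open must be > 0", call. = FALSE)
  k_open * k_ex_open / denom
}

#' Lower bound on the in-cell opening rate
#'
#' Because the exchange rate can never exceed the opening rate
#' (\eqn{k_{ex} \le k_{open}}), a measured in-cell exchange rate is a lower
#' bound on the in-cell opening rate. The intracellular base-catalyst
#' concentration is unknown, so only this one-sided bound is available.
#'
#' @param k_ex in-cell exchange rate, s^-1.
#' @param sd its standard deviation (optional).
#' @return An object of class `"kopen_bound"` carrying the value, sd and
#'   bound semantics.
#' @export
opening_rate_lower_bound <- function(k_ex, sd = NA_real_) {
  if (!is.finite(k_ex) || k_ex < 0)
    stop("k_ex must be finite and >= 0", call. = FALSE)
  structure(list(value = k_ex, sd = sd, bound = "lower"),
            class = "kopen_bound")
}

#' @export
print.kopen_bound <- function(x, ...) {
  cat(sprintf("k_open >= %.4g s^-1", x$value))
  if (is.finite(x$sd)) cat(sprintf(" (sd %.2g)", x$sd))
  cat("  [one-sided lower bound from k_ex]\n")
  invisible(x)
}
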