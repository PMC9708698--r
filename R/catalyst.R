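# Base-catalyst speciation arithmetic for Tris titrations.

#' Tris pKa at a given temperature
#'
#' Linear extrapolation from the 25 degC value with the standard temperature
#' coefficient of Tris. At 18 degC this gives 8.256, conventionally quoted
#' as 8.26.
#'
#' @param temperature_C temperature, degrees Celsius.
#' @param pKa_25 pKa at 25 degC.
#' @param dpKa_dT temperature coefficient, per Kelvin.
#' @return pKa (dimensionless).
#' @export
tris_pKa <- function(temperature_C = 18, pKa_25 = 8.06, dpKa_dT = -0.028) {
  pKa_25 + dpKa_dT * (temperature_C - 25)
}

#' Buffer specification for a titration point
#'
#' @param total_mM total catalyst (Tris) concentration, mM: protonated plus
#'   base form.
#' @param pH sample pH.
#' @param pKa catalyst pKa; the default 8.26 is the Tris value at 18 degC
#'   (see [tris_pKa]), rounded to the two decimals pKa values are normally
#'   quoted with.
#' @param temperature_C temperature metadata, degrees Celsius.
#' @return An object of class `"buffer_spec"`.
#' @export
buffer_spec <- function(total_mM, pH = 8.0, pKa = 8.26, temperature_C = 18) {
  if (!is.finite(total_mM) || total_mM < 0)
    stop("total_mM must be finite and >= 0", call. = FALSE)
  if (pH <= 0 || pH >= 14 || pKa <= 0 || pKa >= 14)
    stop("pH and pKa must lie in (0, 14)", call. = FALSE)
  structure(list(total_mM = total_mM, pH = pH, pKa = pKa,
                 temperature_C = temperature_C),
            class = "buffer_spec")
}

#' @export
print.buffer_spec <- function(x, ...) {
  cat(sprintf("Buffer: %.4g mM total, pH %.2f, pKa %.2f (%.3g mM base form)\n",
              x$total_mM, x$pH, x$pKa,
              base_form_concentration(x$total_mM, x$pH, x$pKa)))
  invisible(x)
}

#' Base-form (catalytically active) concentration of a monoprotic base
#'
#' Henderson-Hasselbalch speciation: the unprotonated fraction of the total
#' concentration `c0` is \eqn{10^{-pKa} / (10^{-pH} + 10^{-pKa})}.
#'
#' @param c0 total concentration, mM (or a [buffer_spec], in which case the
#'   remaining arguments are taken from it).
#' @param pH,pKa see [buffer_spec].
#' @return Base-form concentration, mM.
#' @export
base_form_concentration <- function(c0, pH = 8.0, pKa = 8.26) {
  if (inherits(c0, "buffer_spec")) {
    pH <- c0$pH; pKa <- c0$pKa; c0 <- c0$total_mM
  }
  if (any(c0 < 0)) stop("c0 must be >= 0", call. = FALSE)
  c0 * 10^(-pKa) / (10^(-pH) + 10^(-pKa))
}

#' Total concentration delivering a target base-form concentration
#'
#' Exact algebraic inverse of [base_form_concentration].
#'
#' @param target desired base-form concentration, mM.
#' @inheritParams base_form_concentration
#' @return Total concentration c0, mM.
#' @export
total_for_target_base_form <- function(target, pH = 8.0, pKa = 8.26) {
  if (any(target < 0)) stop("target must be >= 0", call. = FALSE)
  target * (10^(-pH) + 10^(-pKa)) / 10^(-pKa)
}

#' Two-sample swap titration schedule
#'
#' Concentration trajectories for the titration protocol in which two NMR
#' samples at different catalyst concentrations repeatedly exchange equal
#' volumes: per step each sample's concentration becomes
#' `(1 - f) * own + f * other`. pH and crowder concentrations are invariant
#' by construction, which is the point of the protocol.
#'
#' @param c1_start,c2_start starting concentrations of the two samples, mM.
#' @param swap_fraction volume fraction `f` exchanged per step, in [0, 0.5].
#' @param n_steps number of exchange steps.
#' @return A data frame with columns `step` (0..n_steps), `c1`, `c2`.
#' @export
titration_mixing_schedule <- function(c1_start, c2_start, swap_fraction,
                                      n_steps) {
  if (swap_fraction < 0 || swap_fraction > 0.5)
    stop("swap_fraction must lie in [0, 0.5]", call. = FALSE)
  if (c1_start < 0 || c2_start < 0)
    stop("concentrations must be >= 0", call. = FALSE)
  c1 <- numeric(n_steps + 1); c2 <- numeric(n_steps + 1)
  c1[1] <- c1_start; c2[1] <- c2_start
  f <- swap_fraction
  for (k in seq_len(n_steps)) {
    c1[k + 1] <- (1 - f) * c1[k] + f * c2[k]
    c2[k + 1] <- (1 - f) * c2[k] + f * c1[k]
  }
  data.frame(step = 0:n_steps, c1 = c1, c2 = c2)
}
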