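# Intensity-series container: per-residue signal intensity versus delay time
# with acquisition order and spectral noise level.

#' Intensity series for one residue under one condition
#'
#' A data frame of (delay, intensity) pairs plus the order in which the
#' spectra were actually recorded (delays are typically acquired in scrambled
#' order) and the spectral noise standard deviation, in the same arbitrary
#' units as the intensities.
#'
#' @param delays delay times, s (>= 0).
#' @param intensities signal intensities, arbitrary units.
#' @param residue residue label, e.g. `"G4"`.
#' @param condition condition label: `"in_vitro"`, `"in_cell"`, or
#'   `"crowder:<name>"`; free-form suffixes such as `"in_vitro:300"` are
#'   allowed.
#' @param noise_sd spectral noise sd (one value per series), intensity units.
#' @param acq_order permutation of `seq_along(delays)` giving, for each row,
#'   its rank in acquisition time.
#' @return An object of class `"intensity_series"` (a data frame with columns
#'   `delay_s`, `intensity`, `acq_order` and attributes `residue`,
#'   `condition`, `noise_sd`).
#' @export
intensity_series <- function(delays, intensities, residue = "res",
                             condition = "in_vitro", noise_sd = 0,
                             acq_order = seq_along(delays)) {
  if (length(delays) != length(intensities))
    stop("delays and intensities must have the same length", call. = FALSE)
  if (any(!is.finite(delays)) || any(delays < 0))
    stop("delays must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(intensities)))
    stop("intensities must be finite", call. = FALSE)
  if (!setequal(acq_order, seq_along(delays)))
    stop("acq_order must be a permutation of the row indices", call. = FALSE)
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop("noise_sd must be finite and >= 0", call. = FALSE)
  structure(
    data.frame(delay_s = as.numeric(delays),
               intensity = as.numeric(intensities),
               acq_order = as.integer(acq_order)),
    residue = residue, condition = condition, noise_sd = noise_sd,
    class = c("intensity_series", "data.frame"))
}

#' @export
print.intensity_series <- function(x, ...) {
  cat(sprintf("Intensity series: residue %s, condition %s, noise sd %.3g\n",
              attr(x, "residue"), attr(x, "condition"), attr(x, "noise_sd")))
  print.data.frame(x, ...)
  invisible(x)
}

series_noise_sd <- function(series) attr(series, "noise_sd")
series_residue  <- function(series) attr(series, "residue")
series_condition <- function(series) attr(series, "condition")

# rebuild a series with new intensities, keeping metadata
series_with_intensities <- function(series, intensities) {
  intensity_series(series$delay_s, intensities,
                   residue = attr(series, "residue"),
                   condition = attr(series, "condition"),
                   noise_sd = attr(series, "noise_sd"),
                   acq_order = series$acq_order)
}
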