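# From per-concentration exchange rates to the opening rate, and the
# one-sided in-cell classification.

#' Assemble a catalyst titration series
#'
#' Converts per-buffer exchange-rate estimates into a titration over the
#' *base-form* catalyst concentration (the catalytically active species),
#' sorted ascending. Duplicate concentrations are collapsed to their mean
#' with a warning.
#'
#' @param results list of `"kex_fit"` objects, one per buffer point.
#' @param buffers list of [buffer_spec] objects, parallel to `results`.
#' @param residue,condition labels carried on the series.
#' @return An object of class `"titration_series"`: data frame with columns
#'   `base_mM`, `k_ex`, `sd`.
#' @export
build_titration <- function(results, buffers, residue = "res",
                            condition = "in_vitro") {
  if (length(results) < 2)
    stop("a titration needs at least 2 points", call. = FALSE)
  if (length(results) != length(buffers))
    stop("results and buffers must be parallel", call. = FALSE)
  base <- vapply(buffers, base_form_concentration, 0)
  kex <- vapply(results, function(f) {
    if (is.finite(f$mc_mean)) f$mc_mean else f$k_ex
  }, 0)
  sds <- vapply(results, function(f) {
    if (f$n_mc > 0) f$mc_sd else NA_real_
  }, 0)
  df <- data.frame(base_mM = base, k_ex = kex, sd = sds)
  if (anyDuplicated(df$base_mM)) {
    warning("duplicate base-form concentrations collapsed to their mean")
    df <- do.call(rbind, lapply(split(df, df$base_mM), function(g) {
      data.frame(base_mM = g$base_mM[1], k_ex = mean(g$k_ex),
                 sd = mean(g$sd))
    }))
  }
  df <- df[order(df$base_mM), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, residue = residue, condition = condition,
            class = c("titration_series", "data.frame"))
}

# bare-numbers constructor used internally and in tests
titration_series <- function(base_mM, k_ex, sd = rep(NA_real_, length(k_ex)),
                             residue = "res", condition = "in_vitro") {
  o <- order(base_mM)
  structure(data.frame(base_mM = base_mM[o], k_ex = k_ex[o], sd = sd[o]),
            residue = residue, condition = condition,
            class = c("titration_series", "data.frame"))
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("Titration series: residue %s, condition %s\n",
              attr(x, "residue"), attr(x, "condition")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Opening rate from the titration plateau
#'
#' At high base-catalyst concentration the open-state exchange outruns
#' closing (EX1 limit) and the observed exchange rate saturates at the
#' opening rate; the maximum k_ex over the titration is therefore taken as
#' k_open, carrying that point's Monte-Carlo sd. If the two highest-
#' concentration points differ by more than `sd_multiplier` combined sds the
#' series has not plateaued and the estimate is flagged.
#'
#' @param series a `"titration_series"` (>= 2 points).
#' @param sd_multiplier separation multiple used for the plateau check.
#' @return An object of class `"kopen_estimate"`: `k_open`, `sd`, `plateau`
#'   (logical), `method = "plateau"`.
#' @export
kopen_from_plateau <- function(series, sd_multiplier = 2) {
  stopifnot(inherits(series, "titration_series"))
  if (nrow(series) < 2)
    stop("a titration needs at least 2 points", call. = FALSE)
  i_max <- which.max(series$k_ex)
  n <- nrow(series)
  s1 <- series$sd[n - 1]; s2 <- series$sd[n]
  comb <- sqrt(sum(c(s1, s2)^2, na.rm = TRUE))
  plateau <- abs(series$k_ex[n] - series$k_ex[n - 1]) <= sd_multiplier * comb
  structure(list(k_open = series$k_ex[i_max], sd = series$sd[i_max],
                 plateau = plateau, method = "plateau",
                 residue = attr(series, "residue"),
                 condition = attr(series, "condition")),
            class = "kopen_estimate")
}

#' Opening rate and half-saturation from a saturation fit
#'
#' Under base catalysis the open-state exchange rate is proportional to the
#' base-form concentration, \eqn{k_{ex,open} = k_B [B]}, so
#' \deqn{k_{ex}([B]) = \frac{k_{open} [B]}{K_{1/2} + [B]}, \qquad
#'       K_{1/2} = k_{close}/k_B.}
#' This fits both parameters by least squares — an extension of the plateau
#' rule that uses the whole titration; the result is labelled with
#' `method = "saturation_fit"`.
#'
#' @param series a `"titration_series"` (>= 3 points).
#' @return A `"kopen_estimate"` with additional fields `K_half`,
#'   `K_half_se`.
#' @export
fit_saturation_model <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  if (nrow(series) < 3)
    stop("the saturation fit needs at least 3 points", call. = FALSE)
  kmax <- max(series$k_ex)
  half_idx <- which.min(abs(series$k_ex - kmax / 2))
  K0 <- max(series$base_mM[half_idx], min(series$base_mM[series$base_mM > 0],
                                          na.rm = TRUE) / 10, 1e-3)
  dat <- data.frame(B = series$base_mM, y = series$k_ex)
  fit <- try(minpack.lm::nlsLM(y ~ k_open * B / (K_half + B), data = dat,
                               start = list(k_open = kmax, K_half = K0),
                               lower = c(0, 0)),
             silent = TRUE)
  if (inherits(fit, "try-error"))
    stop("saturation fit failed to converge: ",
         attr(fit, "condition")$message, call. = FALSE)
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(k_open = NA_real_, K_half = NA_real_))
  structure(list(k_open = unname(est["k_open"]), sd = unname(se["k_open"]),
                 K_half = unname(est["K_half"]),
                 K_half_se = unname(se["K_half"]),
                 plateau = NA, method = "saturation_fit",
                 residue = attr(series, "residue"),
                 condition = attr(series, "condition")),
            class = "kopen_estimate")
}

#' @export
print.kopen_estimate <- function(x, ...) {
  cat(sprintf("k_open (%s, %s) = %.4g s^-1", x$residue, x$method, x$k_open))
  if (is.finite(x$sd)) cat(sprintf(" (+/- %.2g)", x$sd))
  if (x$method == "plateau" && !isTRUE(x$plateau))
    cat("  [titration not plateaued]")
  if (x$method == "saturation_fit")
    cat(sprintf(", K_1/2 = %.3g mM", x$K_half))
  cat("\n")
  invisible(x)
}

#' Classify in-cell base-pair opening against the in vitro rate
#'
#' Because the in-cell exchange rate is only a *lower bound* on the in-cell
#' opening rate, the comparison is one-sided: the verdict is
#' `"increased_in_cell"` when the in-cell exchange rate clearly exceeds the
#' in vitro opening rate — i.e. when
#' `k_ex_incell - m * sd_incell > k_open_invitro + m * sd_invitro` with
#' separation multiplier `m` — and `"indeterminate"` otherwise. A decrease
#' can never be concluded from the bound.
#'
#' @param k_open_invitro in vitro opening rate, s^-1 (or a
#'   `"kopen_estimate"`).
#' @param sd_invitro its sd.
#' @param k_ex_incell in-cell exchange rate, s^-1 (or a `"kex_fit"`).
#' @param sd_incell its sd.
#' @param sd_multiplier separation multiple `m`.
#' @param residue label carried on the result.
#' @return An object of class `"opening_comparison"`.
#' @export
classify_in_cell_opening <- function(k_open_invitro, sd_invitro,
                                     k_ex_incell, sd_incell,
                                     sd_multiplier = 1, residue = "res") {
  if (inherits(k_open_invitro, "kopen_estimate")) {
    residue <- k_open_invitro$residue
    sd_invitro <- k_open_invitro$sd
    k_open_invitro <- k_open_invitro$k_open
  }
  if (inherits(k_ex_incell, "kex_fit")) {
    sd_incell <- k_ex_incell$mc_sd
    k_ex_incell <- if (is.finite(k_ex_incell$mc_mean))
      k_ex_incell$mc_mean else k_ex_incell$k_ex
  }
  increased <- (k_ex_incell - sd_multiplier * sd_incell) >
    (k_open_invitro + sd_multiplier * sd_invitro)
  structure(list(residue = residue,
                 k_open_invitro = k_open_invitro, sd_invitro = sd_invitro,
                 k_ex_incell = k_ex_incell, sd_incell = sd_incell,
                 sd_multiplier = sd_multiplier,
                 verdict = if (increased) "increased_in_cell" else
                   "indeterminate"),
            class = "opening_comparison")
}

#' @export
print.opening_comparison <- function(x, ...) {
  cat(sprintf(
    "%s: k_open(in vitro) = %.3g +/- %.2g, k_ex(in cell) = %.3g +/- %.2g -> %s\n",
    x$residue, x$k_open_invitro, x$sd_invitro, x$k_ex_incell, x$sd_incell,
    x$verdict))
  invisible(x)
}

#' Tabulate opening comparisons
#'
#' @param comparisons list of `"opening_comparison"` objects.
#' @return A data frame mirroring the per-residue report layout: residue,
#'   in vitro k_open with sd, in-cell k_ex with sd, verdict.
#' @export
comparison_report <- function(comparisons) {
  do.call(rbind, lapply(comparisons, function(x) {
    data.frame(residue = x$residue,
               k_open_invitro = x$k_open_invitro, sd_invitro = x$sd_invitro,
               k_ex_incell = x$k_ex_incell, sd_incell = x$sd_incell,
               verdict = x$verdict)
  }))
}
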