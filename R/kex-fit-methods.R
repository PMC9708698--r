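# Standard modelling methods for the "kex_fit" class.

#' @export
print.kex_fit <- function(x, ...) {
  cat(sprintf("Imino proton exchange fit (%s, %s)\n",
              series_residue(x$series), series_condition(x$series)))
  cat(sprintf("  k_ex = %.4g s^-1  (I0 = %.4g, rss = %.3g, %s)\n",
              x$k_ex, x$I0, x$rss,
              if (x$converged) "converged" else "NOT converged"))
  if (x$n_mc > 0) {
    cat(sprintf("  Monte Carlo (n = %d): %.4g +/- %.2g s^-1",
                x$n_mc, x$mc_mean, x$mc_sd))
    if (x$n_fail > 0) cat(sprintf("  [%d replicate failures%s]", x$n_fail,
                                  if (x$mc_flagged) ", FLAGGED" else ""))
    cat("\n")
  }
  invisible(x)
}

#' @export
summary.kex_fit <- function(object, ...) {
  out <- list(
    residue = series_residue(object$series),
    condition = series_condition(object$series),
    k_ex = object$k_ex, I0 = object$I0,
    rss = object$rss, converged = object$converged,
    R1a = object$rates$R1a, R1w = object$rates$R1w,
    n_delays = nrow(object$series),
    mc_mean = object$mc_mean, mc_sd = object$mc_sd,
    n_mc = object$n_mc, n_fail = object$n_fail,
    mc_flagged = object$mc_flagged)
  class(out) <- "summary.kex_fit"
  out
}

#' @export
print.summary.kex_fit <- function(x, ...) {
  cat(sprintf("Exchange-rate fit: residue %s, condition %s\n",
              x$residue, x$condition))
  cat(sprintf("  fixed rates: R1a = %.4g, R1w = %.4g s^-1\n", x$R1a, x$R1w))
  cat(sprintf("  k_ex (point) = %.4g s^-1, I0 = %.4g over %d delays (rss %.3g)\n",
              x$k_ex, x$I0, x$n_delays, x$rss))
  if (x$n_mc > 0)
    cat(sprintf("  k_ex (MC, n = %d) = %.4g +/- %.2g s^-1 (%d failures)\n",
                x$n_mc, x$mc_mean, x$mc_sd, x$n_fail))
  invisible(x)
}

#' @export
coef.kex_fit <- function(object, ...) {
  c(k_ex = object$k_ex, I0 = object$I0)
}

#' Predicted intensities from a fitted exchange model
#'
#' @param object a `"kex_fit"`.
#' @param newdata optional numeric vector of delays (s); defaults to the
#'   delays used in the fit.
#' @param type `"intensity"` (amplitude-scaled) or `"ratio"` (I(t)/I0).
#' @param ... unused.
#' @export
predict.kex_fit <- function(object, newdata = NULL,
                            type = c("intensity", "ratio"), ...) {
  type <- match.arg(type)
  t_new <- if (is.null(newdata)) object$series$delay_s else newdata
  r <- intensity_ratio(t_new, object$k_ex, object$rates,
                       inversion_efficiency = object$inversion_efficiency)
  if (type == "intensity") object$I0 * r else r
}

#' @export
residuals.kex_fit <- function(object, ...) object$residuals

#' @export
fitted.kex_fit <- function(object, ...) object$fitted

#' Simulate replicate series from a fitted exchange model
#'
#' Draws `nsim` intensity series from the fitted curve with Gaussian noise at
#' the series' spectral noise sd — the same generative assumption the
#' Monte-Carlo error propagation perturbs around.
#'
#' @param object a `"kex_fit"`.
#' @param nsim number of replicates.
#' @param seed optional seed (global RNG state restored on exit).
#' @param ... unused.
#' @return A list of [intensity_series].
#' @export
simulate.kex_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(seed)
  }
  sigma <- series_noise_sd(object$series)
  lapply(seq_len(nsim), function(i) {
    series_with_intensities(
      object$series,
      object$fitted + stats::rnorm(nrow(object$series), sd = sigma))
  })
}

#' Plot a transfer series and its fitted curve
#'
#' @param x a `"kex_fit"`.
#' @param ... passed to [graphics::plot].
#' @export
plot.kex_fit <- function(x, ...) {
  s <- x$series
  t_fine <- seq(0, max(s$delay_s), length.out = 200)
  graphics::plot(s$delay_s, s$intensity, xlab = "delay time (s)",
                 ylab = "intensity",
                 main = sprintf("%s (%s): k_ex = %.3g s^-1",
                                series_residue(s), series_condition(s),
                                x$k_ex), ...)
  sigma <- series_noise_sd(s)
  if (is.finite(sigma) && sigma > 0)
    graphics::arrows(s$delay_s, s$intensity - sigma,
                     s$delay_s, s$intensity + sigma,
                     angle = 90, code = 3, length = 0.03)
  graphics::lines(t_fine, predict(x, newdata = t_fine), col = "red")
  invisible(x)
}
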