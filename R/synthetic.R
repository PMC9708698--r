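# Synthetic-data generator: every input the pipeline consumes — transfer
# curves, recovery curves, titrations, leakage decay — produced from declared
# ground truth, so all stages are testable without spectra.

#' Published hpRNA20 exchange rates
#'
#' Per-residue imino-proton exchange rates (s^-1, mean +/- sd) of the
#' 20-nucleotide RNA hairpin measured in vitro at 10 mM and 300 mM total
#' Tris and inside living HeLa cells. These published values serve both as
#' the default ground truth of the synthetic-study generator and as inputs
#' to the in-cell classification.
#'
#' @return A data frame with columns `residue`, `kex_10mM`, `sd_10mM`,
#'   `kex_300mM`, `sd_300mM`, `kex_incell`, `sd_incell`.
#' @export
hprna20_rates <- function() {
  data.frame(
    residue    = c("G4", "U14", "G15", "U18", "G19"),
    kex_10mM   = c(0.9, 6.7, 0.7, 1.4, 1.4),
    sd_10mM    = c(0.1, 0.1, 0.1, 0.1, 0.1),
    kex_300mM  = c(1.2, 34.5, 1.1, 12.5, 11.6),
    sd_300mM   = c(0.1, 0.3, 0.1, 0.2, 0.2),
    kex_incell = c(3.0, 6.2, 3.2, 4.2, 6.7),
    sd_incell  = c(0.8, 0.4, 0.8, 0.7, 0.7))
}

#' Two-state kinetics consistent with the published hpRNA20 titration
#'
#' Solves the base-catalysis saturation model
#' \eqn{k_{ex}([B]) = k_{open}[B]/(K_{1/2}+[B])} exactly through the two
#' published titration points of each residue (10 and 300 mM total Tris,
#' i.e. 3.55 and 106.4 mM base form at pH 8.0, pKa 8.26), giving the
#' per-residue `k_open` and `K_half` the generator uses as ground truth.
#' By construction the generated exchange rates at the two published
#' concentrations equal the published values.
#'
#' @return Data frame with columns `residue`, `k_open`, `K_half`.
#' @export
hprna20_truth_kinetics <- function() {
  pub <- hprna20_rates()
  B1 <- base_form_concentration(10, pH = 8.0, pKa = 8.26)
  B2 <- base_form_concentration(300, pH = 8.0, pKa = 8.26)
  K <- (pub$kex_300mM - pub$kex_10mM) /
    (pub$kex_10mM / B1 - pub$kex_300mM / B2)
  k_open <- pub$kex_10mM * (K + B1) / B1
  data.frame(residue = pub$residue, k_open = k_open, K_half = K)
}

#' Default transfer-experiment delays and acquisition order
#'
#' Five delays between 1 and 100 ms, acquired in scrambled order
#' (0.1, 0.001, 0.01, 0.06, 0.03 s) so that slow sample decay is not
#' confounded with the delay dependence.
#'
#' @return List with `delays` (sorted, s) and `acq_order` (rank in
#'   acquisition time for each sorted delay).
#' @export
default_delays <- function() {
  delays <- c(0.001, 0.01, 0.03, 0.06, 0.1)
  acquired <- c(0.1, 0.001, 0.01, 0.06, 0.03)
  list(delays = delays, acq_order = as.integer(match(delays, acquired)))
}

#' Ground truth for a synthetic study
#'
#' Declares everything the generator needs: per-residue two-state kinetics
#' (`k_open`, `k_close` implied via `K_half = k_close/k_B`, catalysis
#' constant `k_B`), the in-cell exchange rate, relaxation rates, amplitudes,
#' noise, leakage, buffer series and delays. Defaults emulate the hpRNA20
#' study: the five imino-bearing residues with kinetics solved exactly
#' through the published 10 and 300 mM Tris exchange rates (see
#' [hprna20_truth_kinetics]), a two-sample swap titration from
#' 10 to 300 mM total Tris at pH 8.0, the five scrambled delays, 1%
#' spectral noise in vitro and 6x that in-cell.
#'
#' @param residues residue labels.
#' @param k_open per-residue opening rates, s^-1.
#' @param K_half per-residue half-saturation base-form concentrations, mM
#'   (`k_close / k_B`).
#' @param kex_incell per-residue in-cell exchange rates, s^-1 (each must not
#'   exceed the corresponding in-cell opening rate; the generator treats it
#'   as the directly observable rate).
#' @param k_B open-state catalysis rate constant, per mM per s. Only the
#'   ratio `k_close = K_half * k_B` matters for the generated data; the
#'   default is a typical near-diffusion-limited proton-transfer value.
#' @param R1a_intrinsic exchange-free imino relaxation rate, s^-1; the
#'   apparent rate entering the transfer model is `R1a_intrinsic + k_ex`.
#' @param R1w water relaxation rate, s^-1.
#' @param I0 reference amplitude (arbitrary units).
#' @param noise_sd in vitro spectral noise sd (intensity units, same scale
#'   as `I0`).
#' @param incell_noise_factor multiplier on `noise_sd` for in-cell spectra.
#' @param leakage total fraction of signal lost across one in-cell
#'   experiment (0 = none).
#' @param buffers list of [buffer_spec] for the in vitro titration; default
#'   is the 8-point two-sample swap schedule between 10 and 300 mM.
#' @param delays,acq_order transfer delays (s) and acquisition ranks.
#' @param seed base RNG seed for [generate_study].
#' @return An object of class `"ground_truth"`.
#' @export
ground_truth <- function(residues = hprna20_rates()$residue,
                         k_open = hprna20_truth_kinetics()$k_open,
                         K_half = NULL,
                         kex_incell = hprna20_rates()$kex_incell,
                         k_B = 2e5,
                         R1a_intrinsic = 2.0, R1w = 0.4,
                         I0 = 1, noise_sd = 0.01,
                         incell_noise_factor = 6,
                         leakage = 0,
                         buffers = NULL,
                         delays = default_delays()$delays,
                         acq_order = default_delays()$acq_order,
                         seed = 1L) {
  n <- length(residues)
  if (is.null(K_half)) {
    K_half <- if (identical(residues, hprna20_truth_kinetics()$residue))
      hprna20_truth_kinetics()$K_half else rep(10, n)
  }
  if (is.null(buffers)) {
    sched <- titration_mixing_schedule(10, 300, 0.25, 3)
    totals <- sort(unique(c(sched$c1, sched$c2)))
    buffers <- lapply(totals, buffer_spec, pH = 8.0, pKa = 8.26)
  }
  stopifnot(length(k_open) == n, length(K_half) == n,
            length(kex_incell) == n,
            all(k_open >= 0), all(K_half >= 0), all(kex_incell >= 0))
  structure(list(residues = residues, k_open = k_open, K_half = K_half,
                 k_close = K_half * k_B, k_B = k_B,
                 kex_incell = kex_incell,
                 R1a_intrinsic = R1a_intrinsic, R1w = R1w, I0 = I0,
                 noise_sd = noise_sd,
                 incell_noise_factor = incell_noise_factor,
                 leakage = leakage, buffers = buffers,
                 delays = delays, acq_order = as.integer(acq_order),
                 seed = as.integer(seed)),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "Ground truth: %d residues, %d titration points, R1a_int = %.3g, R1w = %.3g s^-1\n",
    length(x$residues), length(x$buffers), x$R1a_intrinsic, x$R1w))
  print(data.frame(residue = x$residues, k_open = x$k_open,
                   K_half_mM = x$K_half, kex_incell = x$kex_incell))
  invisible(x)
}

# true overall exchange rate of one residue at one buffer point
truth_kex <- function(truth, i, buffer) {
  B <- base_form_concentration(buffer)
  overall_exchange_rate(truth$k_open[i], truth$k_close[i], truth$k_B * B)
}

#' Generate one water magnetization transfer series
#'
#' Composes the two-state kinetics with the transfer model: the base-form
#' catalyst concentration sets the open-state exchange rate
#' (`k_ex_open = k_B * [B]`), the overall rate follows from the two-state
#' expression, ideal ratios are evaluated with the apparent relaxation rate
#' `R1a_intrinsic + k_ex`, a linear leakage decay is applied in acquisition
#' order, and Gaussian noise of the declared sd is added.
#'
#' @param truth a [ground_truth].
#' @param residue residue label (must be in `truth$residues`).
#' @param buffer a [buffer_spec] for an in vitro point, or `NULL` with
#'   `condition = "in_cell"` to use the residue's in-cell rate.
#' @param condition condition label for the series.
#' @param noise_sd override for the noise sd (default from truth and
#'   condition).
#' @return An [intensity_series] with `noise_sd` recorded.
#' @export
generate_transfer_series <- function(truth, residue, buffer = NULL,
                                     condition = NULL, noise_sd = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  i <- match(residue, truth$residues)
  if (is.na(i)) stop("unknown residue: ", residue, call. = FALSE)
  in_cell <- is.null(buffer)
  kex <- if (in_cell) truth$kex_incell[i] else truth_kex(truth, i, buffer)
  if (is.null(condition))
    condition <- if (in_cell) "in_cell" else
      sprintf("in_vitro:%g", buffer$total_mM)
  if (is.null(noise_sd))
    noise_sd <- truth$noise_sd * if (in_cell) truth$incell_noise_factor else 1
  rates <- relaxation_rates(truth$R1a_intrinsic + kex, truth$R1w)
  ideal <- truth$I0 * intensity_ratio(truth$delays, kex, rates)
  decayed <- ideal * leakage_factors(truth$acq_order, truth$leakage)
  noisy <- decayed + stats::rnorm(length(decayed), sd = noise_sd)
  intensity_series(truth$delays, noisy, residue = residue,
                   condition = condition, noise_sd = noise_sd,
                   acq_order = truth$acq_order)
}

#' Generate a relaxation-recovery series
#'
#' Mono-exponential recovery matching the fitting conventions:
#' `I = I_inf (1 - 2 exp(-R1 t))` for inversion recovery,
#' `I = I_inf (1 - exp(-R1 t))` for saturation recovery, plus Gaussian noise.
#'
#' @param R1 relaxation rate, s^-1.
#' @param kind `"inversion"` or `"saturation"`.
#' @param delays recovery delays, s.
#' @param I_inf equilibrium amplitude.
#' @param noise_sd Gaussian noise sd.
#' @param residue,condition labels.
#' @return An [intensity_series].
#' @export
generate_recovery_series <- function(R1, kind = c("inversion", "saturation"),
                                     delays = c(0.01, 0.05, 0.1, 0.25, 0.5,
                                                1, 2, 4),
                                     I_inf = 1, noise_sd = 0,
                                     residue = "res", condition = "in_vitro") {
  kind <- match.arg(kind)
  ideal <- if (kind == "inversion") I_inf * (1 - 2 * exp(-R1 * delays)) else
    I_inf * (1 - exp(-R1 * delays))
  noisy <- ideal + stats::rnorm(length(delays), sd = noise_sd)
  intensity_series(delays, noisy, residue = residue, condition = condition,
                   noise_sd = noise_sd)
}

#' Spectral noise sd that yields a target exchange-rate uncertainty
#'
#' First-order (delta-method) calibration: for the two-parameter transfer
#' model with Jacobian J over the delay grid, the asymptotic covariance of
#' the estimates is \eqn{\sigma^2 (J^T J)^{-1}}; the intensity noise sd
#' \eqn{\sigma} producing a requested sd of k_ex follows by inversion. Used
#' to emulate studies whose published error bars are known but whose raw
#' noise level is not.
#'
#' @param target_kex_sd requested sd of the fitted k_ex, s^-1.
#' @param k_ex,rates,I0 model parameters at which to linearize.
#' @param delays delay grid, s.
#' @return Intensity noise sd (same units as `I0`).
#' @export
noise_sd_for_kex_sd <- function(target_kex_sd, k_ex, rates,
                                delays = default_delays()$delays, I0 = 1) {
  eps <- max(1e-6, 1e-6 * k_ex)
  g <- intensity_ratio(delays, k_ex, rates)
  dg <- (intensity_ratio(delays, k_ex + eps, rates) -
           intensity_ratio(delays, max(k_ex - eps, 0), rates)) /
    (eps + min(eps, k_ex))
  J <- cbind(I0 * dg, g)  # d/dk_ex, d/dI0
  v <- solve(crossprod(J))[1, 1]
  target_kex_sd / sqrt(v)
}

#' Generate a complete synthetic study on disk
#'
#' Reproduces the experimental design end to end: an in vitro titration over
#' the truth's buffer series and a single-concentration in-cell condition
#' with larger noise, plus per-condition recovery series for the apparent
#' imino relaxation rate and the water relaxation rate. Writes the transfer
#' and recovery tables as TSV and a YAML manifest (seed, truth parameters,
#' file list) next to them.
#'
#' @param truth a [ground_truth].
#' @param dir output directory (created if missing).
#' @return Invisibly, a list with the bundle paths and the in-memory tables.
#' @export
generate_study <- function(truth, dir) {
  stopifnot(inherits(truth, "ground_truth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(truth$seed)

  transfer <- list(); recovery <- list()
  for (i in seq_along(truth$residues)) {
    res <- truth$residues[i]
    for (b in truth$buffers) {
      s <- generate_transfer_series(truth, res, b)
      transfer[[length(transfer) + 1]] <- s
      kex <- truth_kex(truth, i, b)
      recovery[[length(recovery) + 1]] <- generate_recovery_series(
        truth$R1a_intrinsic + kex, "inversion", I_inf = truth$I0,
        noise_sd = truth$noise_sd, residue = res,
        condition = series_condition(s))
    }
    s <- generate_transfer_series(truth, res, NULL)
    transfer[[length(transfer) + 1]] <- s
    recovery[[length(recovery) + 1]] <- generate_recovery_series(
      truth$R1a_intrinsic + truth$kex_incell[i], "inversion",
      I_inf = truth$I0,
      noise_sd = truth$noise_sd * truth$incell_noise_factor,
      residue = res, condition = "in_cell")
  }
  conditions <- unique(vapply(transfer, series_condition, ""))
  for (cond in conditions) {
    noise <- truth$noise_sd *
      if (cond == "in_cell") truth$incell_noise_factor else 1
    recovery[[length(recovery) + 1]] <- generate_recovery_series(
      truth$R1w, "saturation",
      delays = c(0.1, 0.25, 0.5, 1, 2, 4, 8, 16),
      I_inf = truth$I0, noise_sd = noise,
      residue = "water", condition = cond)
  }

  paths <- list(transfer = file.path(dir, "transfer.tsv"),
                recovery = file.path(dir, "recovery.tsv"),
                config = file.path(dir, "config.yaml"))
  write_intensity_table(transfer, paths$transfer)
  write_recovery_table(recovery, paths$recovery)
  cfg <- list(
    seed = truth$seed,
    delays = truth$delays, acq_order = truth$acq_order,
    noise_sd = truth$noise_sd,
    incell_noise_factor = truth$incell_noise_factor,
    leakage = truth$leakage,
    R1a_intrinsic = truth$R1a_intrinsic, R1w = truth$R1w, I0 = truth$I0,
    buffers = lapply(truth$buffers, function(b)
      list(total_mM = b$total_mM, pH = b$pH, pKa = b$pKa)),
    truth = lapply(seq_along(truth$residues), function(i)
      list(residue = truth$residues[i], k_open = truth$k_open[i],
           K_half = truth$K_half[i], kex_incell = truth$kex_incell[i])),
    files = list(transfer = "transfer.tsv", recovery = "recovery.tsv"))
  write_study_config(cfg, paths$config)
  invisible(list(paths = paths, transfer = transfer, recovery = recovery,
                 config = cfg))
}
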