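# shared fixtures, built in code

default_rates <- function() relaxation_rates(2.0, 0.4)

# noiseless transfer series at a given exchange rate
make_transfer <- function(k_ex, rates = default_rates(), I0 = 1,
                          noise_sd = 0, delays = default_delays()$delays,
                          acq_order = default_delays()$acq_order,
                          residue = "res", condition = "in_vitro") {
  ideal <- I0 * intensity_ratio(delays, k_ex, rates)
  noisy <- ideal + if (noise_sd > 0) rnorm(length(delays), sd = noise_sd) else 0
  intensity_series(delays, noisy, residue = residue, condition = condition,
                   noise_sd = noise_sd, acq_order = acq_order)
}

# brute-force all-pairs ensemble contact oracle (independent of the
# vectorized implementation)
brute_force_contacts <- function(models, donor_atoms, target_atoms,
                                 cutoff, min_models, strict = TRUE) {
  at <- models$atoms
  hits <- list()
  for (d in seq_len(nrow(at))) {
    dn <- donor_atoms[[at$resid[d]]]
    if (is.null(dn) || !(at$elety[d] %in% dn)) next
    for (a in seq_len(nrow(at))) {
      if (!(at$elety[a] %in% target_atoms)) next
      n_hit <- 0
      for (m in seq_len(models$n_models)) {
        p <- models$xyz[m, (3 * d - 2):(3 * d)]
        q <- models$xyz[m, (3 * a - 2):(3 * a)]
        dist <- sqrt(sum((p - q)^2))
        ok <- if (strict) dist < cutoff else dist <= cutoff
        if (ok) n_hit <- n_hit + 1
      }
      if (n_hit >= min_models)
        hits[[length(hits) + 1]] <- data.frame(
          donor_resno = at$resno[d], target_resno = at$resno[a],
          target_atom = at$elety[a], n = n_hit)
    }
  }
  if (length(hits)) do.call(rbind, hits) else NULL
}
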