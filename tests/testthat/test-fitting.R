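test_that("noise sd estimation uses the signal-free window", {
  expect_equal(estimate_noise_sigma(rep(3, 100), 1:50), 0)
  set.seed(10)
  trace <- rnorm(10000)
  expect_equal(estimate_noise_sigma(trace, 1:10000), 1.0, tolerance = 0.03)
  expect_error(estimate_noise_sigma(trace, 5), "at least 2")
  expect_error(estimate_noise_sigma(trace, c(1, 1e6)), "outside")
})

test_that("recovery fits round-trip noiseless rates", {
  for (R1 in c(2.0, 0.4)) {
    s <- generate_recovery_series(R1, "inversion")
    f <- fit_inversion_recovery(s)
    expect_equal(f$R1, R1, tolerance = 1e-6)
    expect_true(f$converged)
  }
  s <- generate_recovery_series(0.35, "saturation",
                                delays = c(0.1, 0.5, 1, 2, 4, 8))
  expect_equal(fit_saturation_recovery(s)$R1, 0.35, tolerance = 1e-6)
  # saturation model passes through zero at t = 0
  s0 <- generate_recovery_series(0.35, "saturation", delays = c(0, 1, 2))
  expect_equal(s0$intensity[s0$delay_s == 0], 0)
  flat <- intensity_series(c(0.1, 0.5, 1), rep(1, 3))
  expect_error(fit_inversion_recovery(flat), "flat")
  short <- intensity_series(0.5, 1)
  expect_error(fit_saturation_recovery(short), "3 distinct")
})

test_that("exchange fit recovers generating rates from noiseless curves", {
  rates <- default_rates()
  for (k in c(6.2, 34.5, 0.9)) {   # published in-cell / fast / slow regimes
    f <- fit_exchange_rate(make_transfer(k, rates, I0 = 7.3), rates)
    expect_equal(f$k_ex, k, tolerance = 1e-4)
    expect_true(f$converged)
  }
  # all ratios 1 -> no exchange
  s <- intensity_series(default_delays()$delays, rep(1, 5))
  expect_equal(fit_exchange_rate(s, rates)$k_ex, 0, tolerance = 1e-8)
  expect_error(fit_exchange_rate(intensity_series(c(0.01, 0.1), c(1, 0.5)),
                                 rates), "3 distinct")
})

test_that("exchange fit is invariant to intensity scaling", {
  rates <- default_rates()
  set.seed(3)
  s <- make_transfer(12, rates, noise_sd = 0.01)
  k1 <- fit_exchange_rate(s, rates)$k_ex
  s2 <- intensity_series(s$delay_s, s$intensity * 817.3,
                         noise_sd = 0.01, acq_order = s$acq_order)
  k2 <- fit_exchange_rate(s2, rates)$k_ex
  expect_equal(k2, k1, tolerance = 1e-8)
})

test_that("leakage correction reproduces the linear-decay multipliers", {
  s <- make_transfer(5)
  # acquisition ranks for the sorted delays {1,10,30,60,100} ms are
  # {2,3,5,4,1}; a 16% total loss gives retention 0.96^..0.84 by rank
  corrected <- correct_leakage(s, 0.16)
  mult <- corrected$intensity / s$intensity
  expect_equal(sort(mult), sort(1 / c(1, 0.96, 0.92, 0.88, 0.84)),
               tolerance = 1e-12)
  expect_equal(mult[s$acq_order == 1], 1)
  # multipliers follow acquisition order, not delay order
  expect_equal(mult, 1 / (1 - 0.16 * (s$acq_order - 1) / 4),
               tolerance = 1e-12)
  expect_equal(correct_leakage(s, 0)$intensity, s$intensity)
  expect_error(correct_leakage(s, 1), "total_fraction_lost")
})

test_that("leakage correction restores the undecayed exchange rate", {
  truth <- ground_truth(leakage = 0.16, seed = 5)
  rates <- relaxation_rates(truth$R1a_intrinsic + truth$kex_incell[1],
                            truth$R1w)
  set.seed(5)
  s <- generate_transfer_series(truth, "G4", NULL)  # in-cell, decayed
  m_raw <- monte_carlo_kex(s, rates, n_mc = 50, seed = 6)
  m_cor <- monte_carlo_kex(correct_leakage(s, 0.16), rates, n_mc = 50,
                           seed = 6)
  # corrected estimate recovers the generating rate within the MC error bar
  expect_lt(abs(m_cor$mc_mean - truth$kex_incell[1]), 3 * m_cor$mc_sd)
  # and corrected vs uncorrected agree within combined error bars
  expect_lt(abs(m_cor$mc_mean - m_raw$mc_mean),
            3 * sqrt(m_cor$mc_sd^2 + m_raw$mc_sd^2))
})

test_that("Monte-Carlo propagation is deterministic and degenerates cleanly", {
  rates <- default_rates()
  s <- make_transfer(8, rates, noise_sd = 0)
  m0 <- monte_carlo_kex(s, rates, n_mc = 10, seed = 1)
  expect_equal(m0$mc_sd, 0)
  expect_equal(m0$mc_mean, m0$k_ex)

  set.seed(2)
  s <- make_transfer(8, rates, noise_sd = 0.02)
  a <- monte_carlo_kex(s, rates, n_mc = 25, seed = 99)
  b <- monte_carlo_kex(s, rates, n_mc = 25, seed = 99)
  expect_identical(a$mc_mean, b$mc_mean)
  expect_identical(a$mc_sd, b$mc_sd)
  expect_identical(a$mc_values, b$mc_values)
  expect_false(a$mc_flagged)
  expect_equal(a$n_mc, 25L)
})

test_that("point estimates are nearly unbiased and MC sd is calibrated", {
  rates <- default_rates()
  set.seed(42)
  n_rep <- 200
  k_true <- exp(runif(n_rep, log(0.5), log(40)))
  bias <- numeric(n_rep)
  covered <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    s <- make_transfer(k_true[i], rates, noise_sd = 0.01)
    m <- monte_carlo_kex(s, rates, n_mc = 30, seed = 1000 + i)
    bias[i] <- (m$k_ex - k_true[i]) / k_true[i]
    covered[i] <- abs(m$mc_mean - k_true[i]) <= m$mc_sd
  }
  expect_lt(median(abs(bias)), 0.05)
  expect_gt(mean(covered), 0.58)
  expect_lt(mean(covered), 0.78)
})

test_that("residue-averaged fitting interpolates between the inputs", {
  rates <- default_rates()
  s <- make_transfer(4, rates)
  same <- average_intensity_fit(list(s, s), rates)
  expect_equal(same$k_ex, fit_exchange_rate(s, rates)$k_ex,
               tolerance = 1e-6)
  s1 <- make_transfer(1, rates)
  s9 <- make_transfer(9, rates)
  avg <- average_intensity_fit(list(s1, s9), rates)
  expect_gt(avg$k_ex, 1)
  expect_lt(avg$k_ex, 9)
  expect_error(average_intensity_fit(list(), rates), "non-empty")
  bad <- make_transfer(2, rates, delays = c(0.002, 0.02, 0.04, 0.07, 0.11))
  expect_error(average_intensity_fit(list(s1, bad), rates), "delay grid")
})

test_that("residue averaging of rates has mean/sd semantics", {
  expect_equal(average_kex_over_residues(c(2, 4, 6)),
               list(mean = 4, sd = 2, n = 3L))
  one <- average_kex_over_residues(7.3)
  expect_equal(one$sd, 0)
  expect_equal(average_kex_over_residues(c(6, 2, 4))$mean, 4)
  expect_error(average_kex_over_residues(list()), "at least one")
})

test_that("control on/off ratio matches the transfer model", {
  expect_equal(control_exchange_ratio(2, 2)$ratio, 1)
  r <- relaxation_rates(3, 0.4)
  I0 <- 5
  I_on <- I0 * intensity_ratio(0.1, 5, r)
  cr <- control_exchange_ratio(I_on, I0, sd_on = 0.01, sd_off = 0.01)
  expect_equal(cr$ratio, 0.154, tolerance = 1e-3)
  expect_equal(cr$sd,
               sqrt((0.01 / I0)^2 + (cr$ratio * 0.01 / I0)^2),
               tolerance = 1e-12)
  expect_error(control_exchange_ratio(1, 0), "> 0")
})

test_that("kex_fit behaves like a standard fitted model object", {
  rates <- default_rates()
  set.seed(8)
  s <- make_transfer(12, rates, I0 = 3, noise_sd = 0.01)
  f <- monte_carlo_kex(s, rates, n_mc = 10, seed = 4)
  expect_named(coef(f), c("k_ex", "I0"))
  expect_equal(fitted(f) + residuals(f), s$intensity)
  expect_equal(predict(f, newdata = 0, type = "ratio"), 1)
  expect_equal(predict(f), fitted(f))
  sims <- simulate(f, nsim = 3, seed = 2)
  expect_length(sims, 3)
  expect_s3_class(sims[[1]], "intensity_series")
  out <- capture.output(print(summary(f)))
  expect_true(any(grepl("Monte Carlo|MC", out)))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(f))
})
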