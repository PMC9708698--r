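test_that("noiseless generation composes kinetics with the transfer model", {
  truth <- ground_truth(noise_sd = 0, leakage = 0)
  b <- buffer_spec(300)
  s <- generate_transfer_series(truth, "U14", b)
  B <- base_form_concentration(b)
  kex <- overall_exchange_rate(truth$k_open[2], truth$k_close[2],
                               truth$k_B * B)
  rates <- relaxation_rates(truth$R1a_intrinsic + kex, truth$R1w)
  expect_equal(s$intensity, truth$I0 * intensity_ratio(s$delay_s, kex, rates),
               tolerance = 1e-12)
  expect_equal(attr(s, "noise_sd"), 0)
  expect_error(generate_transfer_series(truth, "X99", b), "unknown residue")
})

test_that("generation is seed-deterministic", {
  truth <- ground_truth(seed = 11)
  b <- buffer_spec(50)
  set.seed(truth$seed); s1 <- generate_transfer_series(truth, "G4", b)
  set.seed(truth$seed); s2 <- generate_transfer_series(truth, "G4", b)
  expect_identical(s1$intensity, s2$intensity)
})

test_that("high-catalyst generation yields a plateau near the opening rate", {
  truth <- ground_truth(noise_sd = 0.002)
  set.seed(21)
  top <- buffer_spec(300)
  i <- match("G4", truth$residues)
  kex_top <- overall_exchange_rate(truth$k_open[i], truth$k_close[i],
                                   truth$k_B * base_form_concentration(top))
  s <- generate_transfer_series(truth, "G4", top)
  rates <- relaxation_rates(truth$R1a_intrinsic + kex_top, truth$R1w)
  f <- fit_exchange_rate(s, rates)
  expect_equal(f$k_ex, kex_top, tolerance = 0.03)
  expect_equal(f$k_ex, truth$k_open[i], tolerance = 0.08)
})

test_that("default truth reproduces the published titration points exactly", {
  truth <- ground_truth()
  pub <- hprna20_rates()
  b_low <- base_form_concentration(10)
  b_high <- base_form_concentration(300)
  for (i in seq_along(truth$residues)) {
    expect_equal(overall_exchange_rate(truth$k_open[i], truth$k_close[i],
                                       truth$k_B * b_low),
                 pub$kex_10mM[i], tolerance = 1e-10)
    expect_equal(overall_exchange_rate(truth$k_open[i], truth$k_close[i],
                                       truth$k_B * b_high),
                 pub$kex_300mM[i], tolerance = 1e-10)
  }
  expect_true(all(truth$k_open >= pub$kex_300mM))
})

test_that("recovery generator round-trips within noise", {
  s <- generate_recovery_series(1.7, "inversion", noise_sd = 0)
  expect_equal(fit_inversion_recovery(s)$R1, 1.7, tolerance = 1e-8)
  set.seed(13)
  s2 <- generate_recovery_series(1.7, "inversion", noise_sd = 0.01)
  f <- fit_inversion_recovery(s2)
  expect_lt(abs(f$R1 - 1.7), 2 * 1.7 * 0.1)
  set.seed(13); a <- generate_recovery_series(1, "saturation", noise_sd = 0.01)
  set.seed(13); b <- generate_recovery_series(1, "saturation", noise_sd = 0.01)
  expect_identical(a$intensity, b$intensity)
})

test_that("generated in-cell rates respect the opening-rate bound", {
  # fitted in-cell k_ex must not exceed the generating in-cell opening rate
  # (of which the declared k_ex is a lower bound) by more than 3 MC sd
  truth <- ground_truth()
  rates_list <- lapply(seq_along(truth$residues), function(i)
    relaxation_rates(truth$R1a_intrinsic + truth$kex_incell[i], truth$R1w))
  set.seed(31)
  n_runs <- 60
  ok <- logical(n_runs)
  for (r in seq_len(n_runs)) {
    i <- (r - 1) %% length(truth$residues) + 1
    s <- generate_transfer_series(truth, truth$residues[i], NULL)
    m <- monte_carlo_kex(s, rates_list[[i]], n_mc = 25, seed = 500 + r)
    ok[r] <- m$k_ex <= truth$kex_incell[i] + 3 * m$mc_sd
  }
  expect_gte(mean(ok), 0.99)
})

test_that("noise realizations are independent across delays and residues", {
  truth <- ground_truth(noise_sd = 0.05)
  set.seed(17)
  resid <- unlist(lapply(1:80, function(j) {
    s <- generate_transfer_series(truth, "G4", buffer_spec(100))
    kex <- overall_exchange_rate(truth$k_open[1], truth$k_close[1],
                                 truth$k_B *
                                   base_form_concentration(buffer_spec(100)))
    rates <- relaxation_rates(truth$R1a_intrinsic + kex, truth$R1w)
    s$intensity - intensity_ratio(s$delay_s, kex, rates)
  }))
  n <- length(resid)
  r1 <- cor(resid[-1], resid[-n])
  expect_lt(abs(r1), 2.5 / sqrt(n))   # lag-1 autocorrelation ~ 0
})

test_that("noise calibration hits a requested k_ex uncertainty", {
  rates <- default_rates()
  sig <- noise_sd_for_kex_sd(1.1, 36.1, rates)
  set.seed(23)
  sds <- replicate(8, {
    s <- make_transfer(36.1, rates, noise_sd = sig)
    monte_carlo_kex(s, rates, n_mc = 40)$mc_sd
  })
  expect_equal(mean(sds), 1.1, tolerance = 0.25)
})

test_that("a study bundle is written, re-read losslessly, and reproducible", {
  dir <- withr::local_tempdir()
  truth <- ground_truth(seed = 9)
  bundle <- generate_study(truth, dir)
  expect_true(file.exists(bundle$paths$transfer))
  expect_true(file.exists(bundle$paths$config))

  back <- read_intensity_table(bundle$paths$transfer)
  expect_length(back, length(bundle$transfer))
  orig <- bundle$transfer[[1]]
  key <- paste(attr(orig, "residue"), attr(orig, "condition"), sep = "|")
  expect_equal(back[[key]]$intensity, orig$intensity, tolerance = 0)
  expect_equal(attr(back[[key]], "noise_sd"), attr(orig, "noise_sd"))

  dir2 <- withr::local_tempdir()
  bundle2 <- generate_study(truth, dir2)
  expect_identical(readLines(bundle$paths$transfer),
                   readLines(bundle2$paths$transfer))

  cfg <- read_study_config(bundle$paths$config)
  expect_equal(cfg$seed, 9)
  expect_equal(length(cfg$truth), 5)

  empty <- ground_truth(residues = character(0), k_open = numeric(0),
                        K_half = numeric(0), kex_incell = numeric(0))
  dir3 <- withr::local_tempdir()
  b3 <- generate_study(empty, dir3)
  expect_length(read_intensity_table(b3$paths$transfer), 0)
})
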