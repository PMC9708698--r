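make_fit <- function(k, sd = 0.1) {
  # minimal kex_fit stand-in with MC fields populated
  rates <- default_rates()
  f <- fit_exchange_rate(make_transfer(k, rates), rates)
  f$mc_mean <- k; f$mc_sd <- sd; f$n_mc <- 50L
  f
}

test_that("titrations are keyed by base-form concentration and sorted", {
  buffers <- list(buffer_spec(300), buffer_spec(10))
  ts <- build_titration(list(make_fit(34.5, 0.3), make_fit(6.7, 0.1)),
                        buffers, residue = "U14")
  expect_equal(ts$base_mM,
               base_form_concentration(c(10, 300), 8, 8.26),
               tolerance = 1e-10)
  expect_equal(ts$base_mM, c(3.55, 106.4), tolerance = 1e-3)
  expect_equal(ts$k_ex, c(6.7, 34.5))
  expect_error(build_titration(list(make_fit(1)), list(buffer_spec(10))),
               "at least 2")
  expect_warning(
    dup <- build_titration(list(make_fit(2), make_fit(4), make_fit(10)),
                           list(buffer_spec(10), buffer_spec(10),
                                buffer_spec(300))),
    "duplicate")
  expect_equal(dup$k_ex, c(3, 10))
})

test_that("plateau rule takes the maximum and flags rising tails", {
  ts <- titration_series(c(3.55, 106.4), c(6.7, 34.5), c(0.1, 0.3),
                         residue = "U14")
  est <- kopen_from_plateau(ts)
  expect_equal(est$k_open, 34.5)
  expect_equal(est$sd, 0.3)
  expect_false(est$plateau)   # two points still rising by >> combined sd

  const <- titration_series(c(10, 50, 100), rep(5, 3), rep(0.2, 3))
  est2 <- kopen_from_plateau(const)
  expect_equal(est2$k_open, 5)
  expect_true(est2$plateau)

  rising <- titration_series(c(10, 50, 100), c(2, 5, 9), rep(0.1, 3))
  est3 <- kopen_from_plateau(rising)
  expect_equal(est3$k_open, 9)
  expect_false(est3$plateau)

  # max semantics dominate every point
  set.seed(6)
  for (i in 1:20) {
    k <- runif(5, 0, 40)
    e <- kopen_from_plateau(titration_series(sort(runif(5, 1, 200)), k,
                                             rep(0.1, 5)))
    expect_true(all(e$k_open >= k))
  }
})

test_that("saturation model recovers its parameters and limits", {
  B <- c(2, 10, 50, 150)
  ts <- titration_series(B, 12 * B / (20 + B), rep(0.1, 4))
  fit <- fit_saturation_model(ts)
  expect_equal(fit$k_open, 12, tolerance = 1e-6)
  expect_equal(fit$K_half, 20, tolerance = 1e-6)

  # far above half-saturation the fit agrees with the plateau rule
  B2 <- c(100, 200, 400)
  ts2 <- titration_series(B2, 8 * B2 / (1 + B2), rep(0.1, 3))
  fit2 <- fit_saturation_model(ts2)
  expect_equal(fit2$k_open, 8, tolerance = 0.05)
  expect_equal(kopen_from_plateau(ts2)$k_open, max(ts2$k_ex))

  # concentration-independent series: EX1 regime, K_half ~ 0
  ts3 <- titration_series(c(5, 50, 500), rep(3, 3), rep(0.1, 3))
  fit3 <- fit_saturation_model(ts3)
  expect_lt(fit3$K_half, 1e-3)
  expect_equal(fit3$k_open, 3, tolerance = 1e-4)
  expect_error(fit_saturation_model(titration_series(c(1, 2), c(1, 2))),
               "3 points")
})

test_that("in-cell classification applies the one-sided bound", {
  g4 <- classify_in_cell_opening(1.2, 0.1, 3.0, 0.8, residue = "G4")
  expect_identical(g4$verdict, "increased_in_cell")
  u14 <- classify_in_cell_opening(34.5, 0.3, 6.2, 0.4, residue = "U14")
  expect_identical(u14$verdict, "indeterminate")
  expect_identical(classify_in_cell_opening(5, 0.1, 5, 0.1)$verdict,
                   "indeterminate")
  # monotone: raising the in-cell rate never flips increased -> indeterminate
  flips <- vapply(seq(0, 20, by = 0.5), function(k)
    classify_in_cell_opening(4, 0.2, k, 0.3)$verdict, "")
  first_inc <- match("increased_in_cell", flips)
  expect_true(all(flips[first_inc:length(flips)] == "increased_in_cell"))
})

test_that("comparison report mirrors the per-residue table layout", {
  rep <- comparison_report(list(
    classify_in_cell_opening(1.2, 0.1, 3.0, 0.8, residue = "G4"),
    classify_in_cell_opening(34.5, 0.3, 6.2, 0.4, residue = "U14")))
  expect_named(rep, c("residue", "k_open_invitro", "sd_invitro",
                      "k_ex_incell", "sd_incell", "verdict"))
  expect_equal(rep$verdict, c("increased_in_cell", "indeterminate"))
})
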