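test_that("refractive-index calibration evaluates the Pace cubic", {
  expect_equal(urea_from_refractive_index(1.35, 1.35), 0)
  # dN = 0.0150: 117.66*dN + 29.753*dN^2 + 185.56*dN^3
  expect_equal(urea_from_refractive_index(1.3480, 1.3330),
               117.66 * 0.015 + 29.753 * 0.015^2 + 185.56 * 0.015^3,
               tolerance = 1e-9)
  expect_equal(urea_from_refractive_index(1.3480, 1.3330), 1.772,
               tolerance = 1e-3)
  # monotone in dN
  dn <- seq(0, 0.08, by = 0.005)
  u <- urea_from_refractive_index(1.33 + dn, 1.33)
  expect_true(all(diff(u) > 0))
  expect_error(urea_from_refractive_index(1.33, 1.34),
               class = "cyclofit_validation_error")
  expect_error(urea_from_refractive_index(1.55, 1.40),
               class = "cyclofit_validation_error")
  expect_error(urea_from_refractive_index(1.43, 1.33),
               class = "cyclofit_calibration_error")
})

test_that("two-state signal matches direct evaluation of the model", {
  # midpoint case: exponent 0, exact mean of the baselines
  expect_equal(two_state_signal(3.6, 1000, -10, 3000, 20, 18, 5, 288.15),
               ((1000 - 10 * 3.6) + (3000 + 20 * 3.6)) / 2)
  expect_equal(two_state_signal(3.6, 1000, -10, 3000, 20, 18, 5, 288.15),
               2018)
  # D = 0 with dG >> RT approaches the native intercept
  expect_equal(two_state_signal(0, 1000, -10, 3000, 20, 40, 5, 288.15),
               1000, tolerance = 1e-6)
  # flat baselines: bounded by the two intercepts
  D <- seq(0, 10, by = 0.1)
  y <- two_state_signal(D, 1000, 0, 3000, 0, 18, 5, 288.15)
  expect_true(all(y >= 1000 & y <= 3000))
})

test_that("fraction unfolded has the exact midpoint and limits", {
  for (i in 1:10) {
    p <- random_two_state_params()
    expect_equal(fraction_unfolded(p$dG / p$m, p$dG, p$m, 288.15), 0.5)
  }
  expect_equal(fraction_unfolded(50, 18, 5, 288.15), 1, tolerance = 1e-10)
  expect_equal(fraction_unfolded(0, 200, 5, 288.15), 0, tolerance = 1e-10)
  # K/(1+K) direct evaluation
  RT <- 8.314e-3 * 288.15
  K <- exp((-18 + 5 * 4.6) / RT)
  expect_equal(fraction_unfolded(4.6, 18, 5, 288.15), K / (1 + K))
  expect_equal(fraction_unfolded(4.6, 18, 5, 288.15), 0.890,
               tolerance = 1e-3)
  # strictly increasing in denaturant
  f <- fraction_unfolded(seq(0, 8, 0.5), 18, 5, 288.15)
  expect_true(all(diff(f) > 0))
})

test_that("blank interpolation is linear between knots and refuses extrapolation", {
  blanks <- data.frame(urea_M = 0:10, signal = 10 + 2 * (0:10))
  expect_equal(blank_interpolate(blanks, 0:10), blanks$signal)
  expect_equal(blank_interpolate(data.frame(urea_M = c(0, 1),
                                            signal = c(10, 20)), 0.5), 15)
  const <- data.frame(urea_M = 0:8, signal = rep(7, 9))
  expect_equal(blank_interpolate(const, runif(5, 0, 8)), rep(7, 5))
  expect_error(blank_interpolate(blanks, 10.5),
               class = "cyclofit_extrapolation_error")
})

test_that("noiseless two-state fits recover generating parameters exactly", {
  set.seed(42)
  for (i in 1:5) {
    p <- random_two_state_params()
    ds <- noiseless_unfolding(p)
    f <- fit_two_state(ds)
    expect_true(f$accepted)
    expect_equal(f$dG_kJ_mol, p$dG, tolerance = 1e-6)
    expect_equal(f$m_kJ_mol_M, p$m, tolerance = 1e-6)
    expect_equal(f$yN0, p$yN0, tolerance = 1e-6)
    expect_equal(f$yU0, p$yU0, tolerance = 1e-6)
    expect_equal(f$midpoint_M, p$dG / p$m, tolerance = 1e-6)
  }
})

test_that("midpoint is always recomputed as dG/m", {
  ds <- generate_unfolding(unfolding_preset("cypb"), seed = 11)
  f <- fit_two_state(ds)
  expect_identical(f$midpoint_M, f$dG_kJ_mol / f$m_kJ_mol_M)
})

test_that("shifting all signals shifts only the baselines", {
  p <- list(yN0 = 1000, mN = -10, yU0 = 3000, mU = 20, dG = 18, m = 5)
  ds <- noiseless_unfolding(p)
  shifted <- unfolding_dataset(ds$urea_M, ds$signal + 500,
                               temperature_K = ds$temperature_K)
  f0 <- fit_two_state(ds)
  f1 <- fit_two_state(shifted)
  expect_equal(f1$yN0, f0$yN0 + 500, tolerance = 1e-6)
  expect_equal(f1$yU0, f0$yU0 + 500, tolerance = 1e-6)
  expect_equal(f1$dG_kJ_mol, f0$dG_kJ_mol, tolerance = 1e-6)
  expect_equal(f1$m_kJ_mol_M, f0$m_kJ_mol_M, tolerance = 1e-6)
  expect_equal(f1$midpoint_M, f0$midpoint_M, tolerance = 1e-6)
})

test_that("blank series are interpolated and subtracted before fitting", {
  p <- list(yN0 = 1000, mN = -10, yU0 = 3000, mU = 20, dG = 18, m = 5)
  ds <- noiseless_unfolding(p)
  # a linear buffer background: removing it must restore the clean fit
  blank <- data.frame(urea_M = 0:10, signal = 50 + 5 * (0:10))
  contaminated <- unfolding_dataset(
    ds$urea_M, ds$signal + blank_interpolate(blank, ds$urea_M),
    blank_series = blank)
  f <- fit_two_state(contaminated)
  expect_equal(f$dG_kJ_mol, 18, tolerance = 1e-6)
  expect_equal(f$midpoint_M, 3.6, tolerance = 1e-6)
})

test_that("degenerate and out-of-range data are rejected, not fitted", {
  # flat signal: no transition
  flat <- unfolding_dataset(seq(0, 8, length.out = 30), rep(1000, 30))
  expect_error(fit_two_state(flat), class = "cyclofit_no_transition_error")

  # eligibility gates
  short <- unfolding_dataset(seq(0, 8, length.out = 5),
                             seq(1000, 3000, length.out = 5))
  expect_error(fit_two_state(short), class = "cyclofit_validation_error")
  narrow <- unfolding_dataset(seq(3, 4, length.out = 10), rnorm(10, 2000))
  expect_error(fit_two_state(narrow), class = "cyclofit_validation_error")

  # a midpoint outside the sampled range is not "accepted"
  p <- list(yN0 = 1000, mN = -10, yU0 = 3000, mU = 20, dG = 18, m = 5)
  truth <- unfolding_truth(yN0 = p$yN0, mN = p$mN, yU0 = p$yU0, mU = p$mU,
                           dG_kJ_mol = p$dG, m_kJ_mol_M = p$m,
                           noise_relative = 0, urea_max = 2.4,
                           n_points = 12)
  baseline_only <- generate_unfolding(truth, seed = 1)
  f <- tryCatch(fit_two_state(baseline_only), error = function(e) NULL)
  if (!is.null(f)) expect_false(f$accepted)
})

test_that("replicate summary uses per-replicate midpoints and n-1 SD", {
  fits <- lapply(c(3.5, 3.6, 3.7), function(mid) {
    ds <- noiseless_unfolding(list(yN0 = 1000, mN = -10, yU0 = 3000,
                                   mU = 20, dG = 5 * mid, m = 5))
    fit_two_state(ds)
  })
  s <- summarize_replicates(fits)
  mid_row <- s[s$parameter == "midpoint_M", ]
  expect_equal(mid_row$mean, 3.6, tolerance = 1e-6)
  expect_equal(mid_row$sd, 0.1, tolerance = 1e-5)
  expect_equal(attr(s, "n_replicates"), 3L)

  # identical fits -> SD 0
  same <- summarize_replicates(fits[c(2, 2)])
  expect_equal(same$sd, rep(0, nrow(same)), tolerance = 1e-12)

  expect_error(summarize_replicates(fits[1]),
               class = "cyclofit_insufficient_replicates_error")
})

test_that("titration files round-trip including blank companions", {
  ds <- generate_unfolding(unfolding_preset("cypb"), seed = 3,
                           replicate_id = "repA")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_titration(ds, path)
  ds2 <- read_titration(path)
  expect_equal(ds2$urea_M, ds$urea_M)
  expect_equal(ds2$signal, ds$signal)
  expect_equal(ds2$temperature_K, ds$temperature_K)
  expect_equal(ds2$replicate_id, "repA")
})
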