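test_that("kinetic trace construction enforces sampling invariants", {
  t <- 0:99
  expect_s3_class(kinetic_trace(t, rnorm(100)), "kinetic_trace")
  expect_error(kinetic_trace(0:10, rnorm(11)), ">= 20")
  expect_error(kinetic_trace(rev(t), rnorm(100)), "increasing")
  expect_error(kinetic_trace(t, rnorm(100), enzyme_concentration_M = -1),
               class = "cyclofit_validation_error")
})

test_that("noiseless exponential fits recover generating rates", {
  # single phase, exact recovery
  tr <- manual_trace(rates = 0.05, amps = 80, offset = 1000)
  f <- fit_exponential(tr, 1)
  expect_equal(f$rates_s, 0.05, tolerance = 1e-8)
  expect_equal(f$amplitudes, 80, tolerance = 1e-6)
  expect_equal(f$offset, 1000, tolerance = 1e-8)

  # double phase, both rates within 1% at zero noise
  tr2 <- manual_trace(rates = c(0.20, 0.01), amps = c(50, 50),
                      duration = 600)
  f2 <- fit_exponential(tr2, 2)
  expect_equal(f2$rates_s[1], 0.20, tolerance = 0.01)
  expect_equal(f2$rates_s[2], 0.01, tolerance = 0.01)
  expect_true(all(diff(f2$rates_s) < 0))  # sorted descending

  # constant trace -> no-signal error
  flat <- kinetic_trace(0:299, rep(500, 300))
  expect_error(fit_exponential(flat), class = "cyclofit_no_signal_error")
})

test_that("recovered rates are invariant to intensity scaling", {
  tr <- manual_trace(rates = 0.05, amps = 80, offset = 1000,
                     noise_sd = 5, seed = 9)
  scaled <- kinetic_trace(tr$time_s, tr$intensity * 37)
  f1 <- fit_exponential(tr)
  f2 <- fit_exponential(scaled)
  expect_equal(f2$rates_s, f1$rates_s, tolerance = 1e-6)
  expect_equal(f2$amplitudes, 37 * f1$amplitudes, tolerance = 1e-6)
})

test_that("model selection separates one- from two-phase truths", {
  # clean single-phase: one phase wins
  tr1 <- manual_trace(rates = 0.05, amps = 100, noise_sd = 1, seed = 2)
  sel1 <- select_model(tr1)
  expect_identical(sel1$n_phases, 1L)

  # well-separated two-phase (ratio 20, 50/50): two phases win
  tr2 <- manual_trace(rates = c(0.20, 0.01), amps = c(50, 50),
                      duration = 600, noise_sd = 1, seed = 2)
  sel2 <- select_model(tr2)
  expect_identical(sel2$n_phases, 2L)

  # a second phase below the amplitude gate is not promoted
  tr3 <- manual_trace(rates = c(0.20, 0.01), amps = c(97, 3),
                      duration = 600, noise_sd = 0.5, seed = 2)
  sel3 <- select_model(tr3)
  expect_identical(sel3$n_phases, 1L)
})

test_that("the enzyme-sensitive phase is the one scaling with [E]", {
  conc <- c(0, 2, 6, 10) * 1e-9
  # two-phase traces: fast rate follows the rate law, slow rate fixed
  fits <- lapply(conc, function(E) {
    tr <- manual_trace(rates = c(0.02 + 3e6 * E, 0.004),
                       amps = c(60, 40), duration = 900, conc = E)
    fit_exponential(tr, 2)
  })
  flagged <- identify_enzyme_sensitive_phase(fits)
  expect_true(all(vapply(flagged, `[[`, integer(1),
                         "enzyme_sensitive_phase") == 1L))
  slopes <- attr(flagged, "phase_slopes")
  expect_equal(slopes$slope[slopes$phase == "fast"], 3e6,
               tolerance = 1e-3)

  # single-phase fits: sole phase flagged
  fits1 <- lapply(conc, function(E) {
    tr <- manual_trace(rates = 0.02 + 3e6 * E, amps = 100, conc = E)
    fit_exponential(tr, 1)
  })
  flagged1 <- identify_enzyme_sensitive_phase(fits1)
  expect_true(all(vapply(flagged1, `[[`, integer(1),
                         "enzyme_sensitive_phase") == 1L))

  # both phases concentration-dependent -> ambiguity error
  fits2 <- lapply(conc, function(E) {
    tr <- manual_trace(rates = c(0.02 + 3e6 * E, 0.004 + 1e6 * E),
                       amps = c(60, 40), duration = 900, conc = E)
    fit_exponential(tr, 2)
  })
  expect_error(identify_enzyme_sensitive_phase(fits2),
               class = "cyclofit_ambiguity_error")

  # insufficient design
  expect_error(identify_enzyme_sensitive_phase(fits[1:2]),
               class = "cyclofit_insufficient_design_error")
})

test_that("rate averaging gives per-concentration mean and n-1 SD", {
  mk <- function(rate, E, rep) {
    f <- fit_exponential(manual_trace(rates = rate, amps = 100, conc = E))
    f$enzyme_sensitive_phase <- 1L
    f
  }
  fits <- list(mk(0.10, 0, 1), mk(0.12, 0, 2), mk(0.05, 2e-9, 1))
  avg <- average_rates(fits)
  expect_equal(avg$mean_kapp_s[avg$enzyme_concentration_M == 0], 0.11,
               tolerance = 1e-6)
  expect_equal(avg$sd_kapp_s[avg$enzyme_concentration_M == 0],
               sd(c(0.10, 0.12)), tolerance = 1e-4)
  # single replicate: mean = value, SD absent
  expect_equal(avg$mean_kapp_s[avg$enzyme_concentration_M == 2e-9], 0.05,
               tolerance = 1e-6)
  expect_true(is.na(avg$sd_kapp_s[avg$enzyme_concentration_M == 2e-9]))
})

test_that("specificity regression is exact on exact-line points", {
  E <- c(0, 2, 6, 10) * 1e-9
  pts <- data.frame(enzyme_concentration_M = E,
                    mean_kapp_s = 0.02 + 3e6 * E)
  res <- fit_specificity(pts, peptide_id = "AAPF", condition = "reducing")
  expect_equal(res$kcat_over_KM_M_s, 3e6)
  expect_equal(res$k0_s, 0.02)
  expect_true(res$accepted)

  # constant rates: slope 0, intercept that rate
  flat <- data.frame(enzyme_concentration_M = E, mean_kapp_s = rep(0.04, 4))
  res0 <- fit_specificity(flat)
  expect_equal(res0$kcat_over_KM_M_s, 0)
  expect_equal(res0$k0_s, 0.04)

  # negative slope is reported but not accepted
  neg <- data.frame(enzyme_concentration_M = E,
                    mean_kapp_s = 0.05 - 1e6 * E)
  expect_false(fit_specificity(neg)$accepted)

  expect_error(fit_specificity(pts[1:2, ]),
               class = "cyclofit_insufficient_design_error")
  expect_error(fit_specificity(pts[2:4, ]),
               class = "cyclofit_insufficient_design_error")
})

test_that("condition tags never touch the numeric path", {
  tr_red <- generate_trace(assay_preset("cypa"), "AAPF", 6e-9, seed = 5)
  truth_er <- assay_preset("cypa", condition = "er_mimicking")
  tr_er <- generate_trace(truth_er, "AAPF", 6e-9, seed = 5)
  expect_identical(tr_red$intensity, tr_er$intensity)
  f_red <- fit_exponential(tr_red)
  f_er <- fit_exponential(tr_er)
  expect_identical(f_red$rates_s, f_er$rates_s)
  expect_identical(f_er$condition, "er_mimicking")
})

test_that("trace files round-trip with nM metadata", {
  tr <- generate_trace(assay_preset("cypa"), "AYPF", 2e-9, seed = 8,
                       replicate_id = "rep3")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trace(tr, path)
  tr2 <- read_trace(path)
  expect_equal(tr2$time_s, tr$time_s)
  expect_equal(tr2$intensity, tr$intensity)
  expect_equal(tr2$enzyme_concentration_M, 2e-9)
  expect_identical(tr2$peptide_id, "AYPF")
  expect_identical(tr2$condition, "reducing")
  expect_identical(tr2$replicate_id, "rep3")
})
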