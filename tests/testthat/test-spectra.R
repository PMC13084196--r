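test_that("spectrum construction enforces grid invariants", {
  expect_s3_class(make_cd_spectrum(), "spectrum")
  expect_error(spectrum("cd", c(200, 199), c(1, 2)), "increasing")
  expect_error(spectrum("cd", c(200, 201), c(1, 2, 3)), "equal length")
  expect_error(spectrum("cd", 200, 1), "at least 2")
  expect_error(spectrum("cd", c(-1, 200), c(1, 2)), "positive")
})

test_that("buffer correction subtracts pointwise and guards misuse", {
  wl <- c(200, 201)
  s <- spectrum("cd", wl, c(10, 8))
  b <- spectrum("cd", wl, c(1, 2))
  out <- buffer_correct(s, b)
  expect_equal(out$values, c(9, 6))
  expect_true(out$buffer_corrected)

  # self-subtraction and zero blank
  expect_equal(buffer_correct(s, s)$values, c(0, 0))
  expect_equal(buffer_correct(s, spectrum("cd", wl, c(0, 0)))$values,
               s$values)

  # double correction refused
  expect_error(buffer_correct(out, b), class = "cyclofit_double_correction_error")
  # grid mismatch names the offending wavelength
  b2 <- spectrum("cd", c(200, 202), c(1, 2))
  expect_error(buffer_correct(s, b2), "201", class = "cyclofit_grid_error")
  # kind mismatch
  expect_error(buffer_correct(s, spectrum("fluorescence", wl, c(1, 2))),
               class = "cyclofit_kind_error")
})

test_that("mean residue ellipticity follows the 100*theta/(l c N) form", {
  wl <- c(220, 222)
  # 0.01 deg observed = 10 mdeg as stored
  s <- spectrum("cd", wl, c(10, 10), buffer_corrected = TRUE)
  out <- mean_residue_ellipticity(s, pathlength_cm = 0.1,
                                  concentration_M = 1e-5, n_residues = 178)
  expect_equal(out$mre, rep(100 * 0.01 / (0.1 * 1e-5 * 178), 2))
  expect_equal(out$mre, rep(5.6180e3, 2), tolerance = 1e-4)

  # raw-as-printed variant is exactly 1000-fold larger
  raw <- mean_residue_ellipticity(s, 0.1, 1e-5, 178, mdeg_as_printed = TRUE)
  expect_equal(raw$mre, out$mre * 1000)

  # zero in, zero out; halving with doubled concentration
  z <- spectrum("cd", wl, c(0, 0), buffer_corrected = TRUE)
  expect_equal(mean_residue_ellipticity(z, 0.1, 1e-5, 178)$mre, c(0, 0))
  half <- mean_residue_ellipticity(s, 0.1, 2e-5, 178)
  expect_equal(half$mre, out$mre / 2)

  # linearity in the signal
  a <- runif(1, 0.5, 3)
  s2 <- spectrum("cd", wl, a * s$values, buffer_corrected = TRUE)
  expect_equal(mean_residue_ellipticity(s2, 0.1, 1e-5, 178)$mre,
               a * out$mre)

  expect_error(mean_residue_ellipticity(s, -1, 1e-5, 178),
               class = "cyclofit_validation_error")
  fl <- spectrum("fluorescence", wl, c(1, 1), buffer_corrected = TRUE)
  expect_error(mean_residue_ellipticity(fl, 0.1, 1e-5, 178),
               class = "cyclofit_kind_error")
  expect_error(mean_residue_ellipticity(spectrum("cd", wl, c(1, 1)),
                                        0.1, 1e-5, 178),
               "buffer-corrected")
})

test_that("difference spectrum is an exact pointwise difference", {
  wl <- seq(300, 450, by = 1)
  native <- make_fluor_spectrum(emission_band(wl, 330), wl)
  unfolded <- make_fluor_spectrum(emission_band(wl, 355, height = 120), wl)
  d <- difference_spectrum(unfolded, native)

  expect_equal(d$values, unfolded$values - native$values)
  # additivity: diff + b = a exactly
  expect_equal(d$values + native$values, unfolded$values)
  # antisymmetry
  expect_equal(difference_spectrum(native, unfolded)$values, -d$values)
  # a = b -> zeros
  expect_equal(difference_spectrum(native, native)$values,
               rep(0, length(wl)))

  # extremum sits red of both band centers by construction
  peak_wl <- wl[which.max(abs(d$values))]
  expect_gt(peak_wl, 330)
})

test_that("Beer-Lambert concentration is exact and monotone", {
  expect_equal(concentration_from_a280(0, 8730, 1), 0)
  expect_equal(concentration_from_a280(0.8730, 8730, 1), 1e-4)
  expect_equal(concentration_from_a280(1.6960, 16960, 1), 1e-4)
  expect_error(concentration_from_a280(-0.1, 8730, 1),
               class = "cyclofit_validation_error")

  a <- sort(runif(5))
  expect_true(all(diff(concentration_from_a280(a, 8730, 1)) > 0))
  expect_gt(concentration_from_a280(1, 8730, 1),
            concentration_from_a280(1, 8730, 2))
  expect_gt(concentration_from_a280(1, 8730, 1),
            concentration_from_a280(1, 16960, 1))
})

test_that("scan averaging is the pointwise mean", {
  wl <- 200:210
  scans <- lapply(1:8, function(i) spectrum("cd", wl, rep(i, length(wl))))
  avg <- average_spectra(scans)
  expect_equal(avg$values, rep(mean(1:8), length(wl)))
})

test_that("spectrum files round-trip through delimited text", {
  wl <- seq(195, 250, by = 0.5)
  s <- spectrum("cd", wl, rnorm(length(wl)), buffer_corrected = TRUE,
                meta = list(temperature_C = 15, pathlength_cm = 0.1,
                            buffer = "2 mM HEPES, 10 mM KCl, pH 7.4"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum(s, path)
  s2 <- read_spectrum(path)
  expect_equal(s2$kind, "cd")
  expect_true(s2$buffer_corrected)
  expect_equal(s2$wavelengths_nm, s$wavelengths_nm)
  expect_equal(s2$values, s$values)
  expect_equal(s2$meta$temperature_C, 15)
  expect_equal(s2$meta$buffer, "2 mM HEPES, 10 mM KCl, pH 7.4")

  # text representation is bit-stable under a second cycle
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum(s2, path2)
  expect_identical(readLines(path), readLines(path2))
})
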