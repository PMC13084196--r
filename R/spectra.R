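# Circular-dichroism and fluorescence spectrum handling: construction,
# buffer correction, mean residue ellipticity, difference spectra, and
# Beer-Lambert concentration determination.

#' Construct a spectrum object
#'
#' A `spectrum` holds one wavelength-indexed optical recording, either a
#' circular-dichroism scan (signal in mdeg) or a fluorescence emission
#' scan (arbitrary units), together with acquisition metadata.
#'
#' @param kind `"cd"` or `"fluorescence"`.
#' @param wavelengths_nm Strictly increasing positive wavelength grid (nm).
#' @param values Signal at each wavelength; mdeg for CD, arbitrary units
#'   for fluorescence.
#' @param buffer_corrected Has the buffer blank already been subtracted?
#' @param meta Named list of acquisition metadata; recognized keys include
#'   `temperature_C`, `excitation_nm`, `bandwidths_nm`, `pathlength_cm`,
#'   `protein_concentration_M`, `n_residues`, `buffer`. Stored verbatim.
#' @return An object of class `spectrum`.
#' @export
#' @examples
#' s <- spectrum("cd", 200:250, rnorm(51))
spectrum <- function(kind = c("cd", "fluorescence"), wavelengths_nm, values,
                     buffer_corrected = FALSE, meta = list()) {
  kind <- match.arg(kind)
  wavelengths_nm <- as.numeric(wavelengths_nm)
  values <- as.numeric(values)
  if (length(wavelengths_nm) < 2L) {
    abort("a spectrum needs at least 2 points", "cyclofit_validation_error")
  }
  if (length(values) != length(wavelengths_nm)) {
    abort("wavelengths and values must have equal length",
          "cyclofit_validation_error")
  }
  if (any(!is.finite(wavelengths_nm)) || any(wavelengths_nm <= 0)) {
    abort("wavelengths must be positive and finite",
          "cyclofit_validation_error")
  }
  if (any(diff(wavelengths_nm) <= 0)) {
    abort("wavelengths must be strictly increasing",
          "cyclofit_validation_error")
  }
  structure(
    list(kind = kind, wavelengths_nm = wavelengths_nm, values = values,
         buffer_corrected = isTRUE(buffer_corrected), meta = meta),
    class = "spectrum"
  )
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %s, %d points, %.1f-%.1f nm%s>\n",
              x$kind, length(x$values), min(x$wavelengths_nm),
              max(x$wavelengths_nm),
              if (x$buffer_corrected) ", buffer-corrected" else ""))
  invisible(x)
}

# Grids must agree after rounding to 3 decimals (acquisition interval is
# 0.1 nm); mismatches fail loudly rather than being interpolated.
check_same_grid <- function(a, b) {
  ga <- round(a$wavelengths_nm, 3)
  gb <- round(b$wavelengths_nm, 3)
  if (length(ga) != length(gb) || any(ga != gb)) {
    bad <- if (length(ga) != length(gb)) {
      ga[min(length(ga), length(gb) + 1L)]
    } else {
      ga[which(ga != gb)[1]]
    }
    abort(sprintf("wavelength grids differ (first mismatch near %.3f nm)",
                  bad),
          "cyclofit_grid_error")
  }
  if (a$kind != b$kind) {
    abort(sprintf("spectrum kinds differ: %s vs %s", a$kind, b$kind),
          "cyclofit_kind_error")
  }
  invisible(TRUE)
}

#' Subtract a buffer blank from a sample spectrum
#'
#' Pointwise subtraction of the blank from the sample on an identical
#' wavelength grid. A spectrum can only be corrected once.
#'
#' @param sample A `spectrum`, not yet buffer-corrected.
#' @param blank A `spectrum` of the same kind on the same grid.
#' @return The corrected `spectrum` with `buffer_corrected = TRUE` and the
#'   sample's metadata preserved.
#' @export
buffer_correct <- function(sample, blank) {
  stopifnot(inherits(sample, "spectrum"), inherits(blank, "spectrum"))
  if (isTRUE(sample$buffer_corrected)) {
    abort("sample is already buffer-corrected; refusing double correction",
          "cyclofit_double_correction_error")
  }
  check_same_grid(sample, blank)
  out <- sample
  out$values <- sample$values - blank$values
  out$buffer_corrected <- TRUE
  out
}

#' Mean residue ellipticity from a circular-dichroism spectrum
#'
#' Normalizes a buffer-corrected CD spectrum to mean residue ellipticity,
#' \deqn{[\Theta]_{MRE} = \frac{100\,\Theta_{obs}}{l\,c\,N},}
#' with the observed ellipticity expressed in degrees, the pathlength
#' \eqn{l} in cm, the protein concentration \eqn{c} in mol/L and \eqn{N}
#' the number of residues; the result carries the conventional unit
#' deg cm^2 dmol^-1. Instrument exports report ellipticity in mdeg, so by
#' default the signal is divided by 1000 before the formula is applied;
#' set `mdeg_as_printed = TRUE` to skip that conversion and normalize the
#' raw mdeg values instead (values then come out 1000-fold larger).
#'
#' @param s A buffer-corrected CD `spectrum` (values in mdeg).
#' @param pathlength_cm Cuvette pathlength in cm.
#' @param concentration_M Protein concentration in mol/L.
#' @param n_residues Number of amino-acid residues.
#' @param mdeg_as_printed Normalize raw mdeg without converting to degrees.
#' @return An object of class `mre_spectrum` with fields `wavelengths_nm`,
#'   `mre` and the source metadata.
#' @export
mean_residue_ellipticity <- function(s, pathlength_cm, concentration_M,
                                     n_residues, mdeg_as_printed = FALSE) {
  stopifnot(inherits(s, "spectrum"))
  if (s$kind != "cd") {
    abort("mean residue ellipticity is defined for CD spectra only",
          "cyclofit_kind_error")
  }
  if (!isTRUE(s$buffer_corrected)) {
    abort("spectrum must be buffer-corrected before normalization",
          "cyclofit_validation_error")
  }
  check_positive_scalar(pathlength_cm, "pathlength_cm")
  check_positive_scalar(concentration_M, "concentration_M")
  check_positive_scalar(n_residues, "n_residues")
  if (n_residues < 1) {
    abort("`n_residues` must be >= 1", "cyclofit_validation_error")
  }
  theta_deg <- if (mdeg_as_printed) s$values else s$values / 1000
  mre <- 100 * theta_deg / (pathlength_cm * concentration_M * n_residues)
  structure(
    list(wavelengths_nm = s$wavelengths_nm, mre = mre,
         unit = "deg cm^2 dmol^-1", meta = s$meta),
    class = "mre_spectrum"
  )
}

#' @export
print.mre_spectrum <- function(x, ...) {
  cat(sprintf("<mre_spectrum: %d points, %.1f-%.1f nm, %s>\n",
              length(x$mre), min(x$wavelengths_nm), max(x$wavelengths_nm),
              x$unit))
  invisible(x)
}

#' Difference spectrum between two recordings
#'
#' Pointwise `a - b` on a shared grid, e.g. unfolded-minus-native
#' fluorescence to locate the wavelength of maximal signal change.
#'
#' @param a,b Spectra of the same kind on the same wavelength grid.
#' @return A `spectrum` whose metadata records both sources.
#' @export
difference_spectrum <- function(a, b) {
  stopifnot(inherits(a, "spectrum"), inherits(b, "spectrum"))
  check_same_grid(a, b)
  out <- a
  out$values <- a$values - b$values
  out$meta <- list(minuend = a$meta, subtrahend = b$meta,
                   derived = "difference_spectrum")
  out
}

#' Average repeated scans pointwise
#'
#' Repeated acquisitions of the same sample are averaged at ingest into a
#' single spectrum; per-scan data are not retained.
#'
#' @param spectra List of `spectrum` objects on a common grid.
#' @return The pointwise-mean `spectrum` (metadata from the first scan).
#' @export
average_spectra <- function(spectra) {
  stopifnot(length(spectra) >= 1L,
            all(vapply(spectra, inherits, logical(1), "spectrum")))
  first <- spectra[[1]]
  for (s in spectra[-1]) check_same_grid(first, s)
  vals <- rowMeans(vapply(spectra, `[[`, numeric(length(first$values)),
                          "values"))
  out <- first
  out$values <- vals
  out
}

#' Protein concentration from absorbance at 280 nm
#'
#' Beer-Lambert law, \eqn{c = A / (\varepsilon l)}.
#'
#' @param absorbance Absorbance at 280 nm (dimensionless, >= 0).
#' @param extinction_M_cm Molar extinction coefficient (M^-1 cm^-1),
#'   e.g. 8730 for CypA or 16960 for CypB.
#' @param pathlength_cm Pathlength in cm.
#' @return Molar concentration (mol/L).
#' @export
#' @examples
#' concentration_from_a280(0.8730, 8730, 1)  # 1e-4 M
concentration_from_a280 <- function(absorbance, extinction_M_cm,
                                    pathlength_cm = 1) {
  if (!is.numeric(absorbance) || any(!is.finite(absorbance)) ||
      any(absorbance < 0)) {
    abort("`absorbance` must be non-negative and finite",
          "cyclofit_validation_error")
  }
  check_positive_scalar(extinction_M_cm, "extinction_M_cm")
  check_positive_scalar(pathlength_cm, "pathlength_cm")
  absorbance / (extinction_M_cm * pathlength_cm)
}

#' Read / write a spectrum as delimited text
#'
#' Two columns (wavelength_nm, value) with `# key=value` metadata header
#' lines; recognized keys `kind` and `buffer_corrected` populate the
#' object fields, all others land in `meta`.
#'
#' @param path File path.
#' @return `read_spectrum()` returns a `spectrum`; `write_spectrum()`
#'   returns `path` invisibly.
#' @export
read_spectrum <- function(path) {
  raw <- read_xy_file(path)
  kind <- raw$meta$kind %||% "cd"
  corrected <- isTRUE(raw$meta$buffer_corrected == "true" |
                        raw$meta$buffer_corrected == TRUE)
  meta <- raw$meta[setdiff(names(raw$meta), c("kind", "buffer_corrected"))]
  spectrum(kind, raw$x, raw$y, buffer_corrected = corrected, meta = meta)
}

#' @rdname read_spectrum
#' @param s A `spectrum` to serialize.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "spectrum"))
  meta <- c(list(kind = s$kind,
                 buffer_corrected = if (s$buffer_corrected) "true" else "false"),
            Filter(function(v) is.atomic(v) && length(v) == 1L, s$meta))
  write_xy_file(path, s$wavelengths_nm, s$values, meta,
                columns = c("wavelength_nm", "value"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
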