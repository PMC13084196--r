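#!/usr/bin/env Rscript
# Stage 4: spectral processing demo on synthetic CD and fluorescence
# spectra: buffer correction, mean-residue-ellipticity normalization of
# a CD scan (178-residue protein, 1 mm cuvette, 10 uM), and the
# unfolded-minus-native fluorescence difference spectrum, whose extremum
# marks the most informative detection wavelength for the titrations.

suppressMessages(library(cyclofit))

dir.create("results/spectra", showWarnings = FALSE, recursive = TRUE)

# synthetic far-UV CD scan: alpha/beta protein with the 222 nm shoulder,
# in mdeg, plus a small buffer background
wl_cd <- seq(195, 250, by = 0.5)
band <- function(center, h, w) h * exp(-((wl_cd - center) / w)^2)
cd_sample <- spectrum("cd", wl_cd,
                      band(208, -8, 9) + band(222, -9, 10) + band(193, 14, 6) +
                        0.4,
                      meta = list(pathlength_cm = 0.1,
                                  protein_concentration_M = 1e-5,
                                  n_residues = 178))
cd_blank <- spectrum("cd", wl_cd, rep(0.4, length(wl_cd)))
corrected <- buffer_correct(cd_sample, cd_blank)
mre <- mean_residue_ellipticity(corrected, 0.1, 1e-5, 178)
write_xy <- function(x, y, path, cols) {
  utils::write.table(setNames(data.frame(x, y), cols), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
}
write_xy(mre$wavelengths_nm, mre$mre, "results/spectra/cd_mre.tsv",
         c("wavelength_nm", "mre_deg_cm2_dmol"))
cat(sprintf("MRE at 222 nm: %.3g deg cm^2 dmol^-1\n",
            mre$mre[mre$wavelengths_nm == 222]))

# synthetic fluorescence emission, native vs 6 M urea: unfolding red-
# shifts and quenches the tryptophan band
wl_fl <- seq(295, 450, by = 1)
emis <- function(center, h, w) h * exp(-((wl_fl - center) / w)^2)
native <- spectrum("fluorescence", wl_fl, emis(335, 1000, 25))
unfolded <- spectrum("fluorescence", wl_fl, emis(352, 700, 30))
d <- difference_spectrum(unfolded, native)
write_xy(d$wavelengths_nm, d$values, "results/spectra/difference.tsv",
         c("wavelength_nm", "delta_fluorescence"))
ext <- d$wavelengths_nm[which.max(abs(d$values))]
cat(sprintf("difference-spectrum extremum at %d nm -> detection wavelength for titrations\n",
            ext))

# Beer-Lambert concentrations from A280 with the two extinction
# coefficients used for the cyclophilin constructs
cat(sprintf("A280 = 0.873, eps = 8730: c = %.3g M\n",
            concentration_from_a280(0.873, 8730, 1)))
cat(sprintf("A280 = 1.696, eps = 16960: c = %.3g M\n",
            concentration_from_a280(1.696, 16960, 1)))
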