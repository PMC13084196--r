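# Shared fixture builders: all synthetic, constructed in code at test time.

make_cd_spectrum <- function(values = NULL, wl = seq(195, 250, by = 1),
                             corrected = FALSE) {
  if (is.null(values)) values <- -10 * exp(-((wl - 222) / 10)^2)
  spectrum("cd", wl, values, buffer_corrected = corrected)
}

make_fluor_spectrum <- function(values, wl) {
  spectrum("fluorescence", wl, values)
}

# Gaussian-band fluorescence emission used for difference-spectrum tests:
# the "unfolded" band is red-shifted so the programmed maximum-change
# wavelength is known by construction.
emission_band <- function(wl, center, height = 100, width = 20) {
  height * exp(-((wl - center) / width)^2)
}

random_two_state_params <- function() {
  m <- runif(1, 3, 7)
  mid <- runif(1, 2.5, 5.5)
  list(yN0 = runif(1, 500, 2000), mN = runif(1, -30, 0),
       yU0 = runif(1, 2500, 5000), mU = runif(1, 0, 50),
       dG = m * mid, m = m)
}

noiseless_unfolding <- function(p, n = 30, urea_max = 8, Tk = 288.15) {
  ds_truth <- unfolding_truth(yN0 = p$yN0, mN = p$mN, yU0 = p$yU0,
                              mU = p$mU, dG_kJ_mol = p$dG,
                              m_kJ_mol_M = p$m, temperature_K = Tk,
                              noise_relative = 0, urea_max = urea_max,
                              n_points = n)
  generate_unfolding(ds_truth, seed = 1)
}

# Single- or double-exponential trace built directly (independent of the
# generate_trace code path) for oracle tests.
manual_trace <- function(rates, amps, offset = 1000, duration = 300,
                         dt = 1, conc = 0, noise_sd = 0, seed = 1,
                         peptide = "AAPF") {
  t <- seq(0, duration, by = dt)
  y <- rep(offset, length(t))
  for (i in seq_along(rates)) y <- y - amps[i] * exp(-rates[i] * t)
  if (noise_sd > 0) {
    set.seed(seed)
    y <- y + rnorm(length(y), 0, noise_sd)
  }
  kinetic_trace(t, y, enzyme_concentration_M = conc, peptide_id = peptide)
}
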