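# Seeded synthetic-data generators: urea-unfolding titrations from the
# two-state model and isomerization assays from the rate law
# k_app = k0 + [E] * kcat/KM, each with a ground-truth manifest so every
# analysis stage can be scored by parameter recovery.

#' Ground truth for a synthetic unfolding titration
#'
#' @param yN0,mN Native baseline intercept and slope (a.u., a.u./M).
#' @param yU0,mU Unfolded baseline intercept and slope.
#' @param dG_kJ_mol Free energy of unfolding (kJ/mol, > 0).
#' @param m_kJ_mol_M Cooperativity parameter (kJ mol^-1 M^-1, > 0).
#' @param temperature_K Absolute temperature.
#' @param noise_relative Relative SD of multiplicative Gaussian noise on
#'   the signal (0 for noiseless).
#' @param urea_max Upper end of the titration (M), grid from 0.
#' @param n_points Number of titration points (>= 8).
#' @return An object of class `unfolding_truth`.
#' @export
unfolding_truth <- function(yN0 = 1000, mN = -10, yU0 = 3000, mU = 20,
                            dG_kJ_mol = 18, m_kJ_mol_M = 5,
                            temperature_K = 288.15, noise_relative = 0.01,
                            urea_max = 8, n_points = 30L) {
  check_positive_scalar(dG_kJ_mol, "dG_kJ_mol")
  check_positive_scalar(m_kJ_mol_M, "m_kJ_mol_M")
  check_positive_scalar(temperature_K, "temperature_K")
  if (!is_scalar_number(noise_relative) || noise_relative < 0) {
    abort("`noise_relative` must be >= 0", "cyclofit_validation_error")
  }
  if (n_points < 8L) {
    abort("urea grid needs >= 8 points", "cyclofit_validation_error")
  }
  structure(
    list(yN0 = yN0, mN = mN, yU0 = yU0, mU = mU, dG_kJ_mol = dG_kJ_mol,
         m_kJ_mol_M = m_kJ_mol_M, temperature_K = temperature_K,
         noise_relative = noise_relative, urea_max = urea_max,
         n_points = as.integer(n_points)),
    class = "unfolding_truth"
  )
}

#' Preset unfolding truths
#'
#' `"cypa"` uses dG = 23 kJ/mol, m = 5 kJ/mol/M (midpoint 4.6 M urea);
#' `"cypb"` uses dG = 18, m = 5 (midpoint 3.6 M) — the two cyclophilin
#' stability regimes.
#'
#' @param preset `"cypa"` or `"cypb"`.
#' @param ... Overrides passed to [unfolding_truth()].
#' @export
unfolding_preset <- function(preset = c("cypa", "cypb"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
                 cypa = list(dG_kJ_mol = 23, m_kJ_mol_M = 5),
                 cypb = list(dG_kJ_mol = 18, m_kJ_mol_M = 5))
  do.call(unfolding_truth, utils::modifyList(base, list(...)))
}

#' Generate a synthetic unfolding titration
#'
#' Evaluates the two-state signal on an even urea grid and applies
#' multiplicative Gaussian noise, `signal * (1 + eps)` with
#' `eps ~ N(0, noise_relative)` (`noise_model = "additive"` instead adds
#' `N(0, noise_relative * mean(|signal|))`). Identical `(truth, seed)`
#' pairs yield bit-identical datasets.
#'
#' @param truth An `unfolding_truth`.
#' @param seed Integer seed for the noise draw.
#' @param replicate_id Replicate label stored in the dataset.
#' @param noise_model `"multiplicative"` (photon-flux-proportional,
#'   default) or `"additive"`.
#' @return An `unfolding_dataset` with attribute `truth` recording the
#'   generating parameters and seed.
#' @export
generate_unfolding <- function(truth, seed = 1L, replicate_id = "sim1",
                               noise_model = c("multiplicative",
                                               "additive")) {
  stopifnot(inherits(truth, "unfolding_truth"))
  noise_model <- match.arg(noise_model)
  D <- seq(0, truth$urea_max, length.out = truth$n_points)
  mu <- two_state_signal(D, truth$yN0, truth$mN, truth$yU0, truth$mU,
                         truth$dG_kJ_mol, truth$m_kJ_mol_M,
                         truth$temperature_K)
  y <- with_seed(seed, {
    if (truth$noise_relative == 0) {
      mu
    } else if (noise_model == "multiplicative") {
      mu * (1 + stats::rnorm(length(mu), 0, truth$noise_relative))
    } else {
      mu + stats::rnorm(length(mu), 0, truth$noise_relative * mean(abs(mu)))
    }
  })
  ds <- unfolding_dataset(D, y, temperature_K = truth$temperature_K,
                          replicate_id = replicate_id)
  attr(ds, "truth") <- c(unclass(truth), list(seed = seed,
                                              noise_model = noise_model))
  ds
}

#' Ground truth for a synthetic isomerization assay
#'
#' Defines the generating rate law of a full peptide assay: per-peptide
#' uncatalyzed rate k0 and specificity constant kcat/KM, the enzyme
#' concentration series, replication, trace geometry and noise. The
#' default concentration grid is 0/2/6/10 nM and four replicates per
#' concentration. Fluorescence rises because the cis conformer quenches
#' the fluorophore and peptides enter the aqueous assay predominantly
#' cis; the amplitude parameter encodes that cis-to-trans population
#' shift.
#'
#' @param peptides Character vector of peptide ids.
#' @param k0_s Named (or recycled) uncatalyzed rates per peptide (s^-1).
#' @param kcat_over_KM_M_s Named (or recycled) specificity constants
#'   (M^-1 s^-1).
#' @param enzyme_concentrations_M Concentration series (mol/L) incl. 0.
#' @param n_replicates Replicates per concentration (>= 1).
#' @param duration_s,dt_s Trace length and sampling interval (s).
#' @param amplitude,offset Relaxation amplitude and final fluorescence
#'   (a.u.).
#' @param noise_relative Relative SD of the per-sample Gaussian noise.
#' @param slow_phase Optional enzyme-insensitive contaminant phase:
#'   `NULL` or `list(rate_s, amplitude_fraction)` (fraction of the main
#'   amplitude).
#' @param condition `"reducing"` or `"er_mimicking"` tag for all traces.
#' @param temperature_K Absolute temperature.
#' @return An object of class `assay_truth`.
#' @export
assay_truth <- function(peptides = c("AAPF", "AEPF", "AKPF", "ALPF",
                                     "AYPF"),
                        k0_s = 0.02, kcat_over_KM_M_s = 3e6,
                        enzyme_concentrations_M = c(0, 2, 6, 10) * 1e-9,
                        n_replicates = 4L, duration_s = 300, dt_s = 1,
                        amplitude = 600, offset = 1000,
                        noise_relative = 0.01, slow_phase = NULL,
                        condition = c("reducing", "er_mimicking"),
                        temperature_K = 288.15) {
  condition <- match.arg(condition)
  k0_s <- rep_len(k0_s, length(peptides))
  kcat_over_KM_M_s <- rep_len(kcat_over_KM_M_s, length(peptides))
  names(k0_s) <- names(kcat_over_KM_M_s) <- peptides
  if (any(k0_s <= 0)) {
    abort("k0 must be positive", "cyclofit_validation_error")
  }
  if (any(kcat_over_KM_M_s < 0)) {
    abort("kcat/KM must be non-negative", "cyclofit_validation_error")
  }
  if (any(enzyme_concentrations_M < 0)) {
    abort("enzyme concentrations must be non-negative",
          "cyclofit_validation_error")
  }
  if (duration_s < 3 / min(k0_s)) {
    abort("trace duration must cover >= 3 relaxation times of the slowest k0",
          "cyclofit_validation_error")
  }
  fastest <- max(k0_s + max(enzyme_concentrations_M) * kcat_over_KM_M_s)
  if (dt_s > 1 / (2 * fastest)) {
    abort("sampling interval too coarse for the fastest implied rate",
          "cyclofit_design_error")
  }
  structure(
    list(peptides = peptides, k0_s = k0_s,
         kcat_over_KM_M_s = kcat_over_KM_M_s,
         enzyme_concentrations_M = enzyme_concentrations_M,
         n_replicates = as.integer(n_replicates),
         duration_s = duration_s, dt_s = dt_s,
         amplitude = amplitude, offset = offset,
         noise_relative = noise_relative, slow_phase = slow_phase,
         condition = condition, temperature_K = temperature_K),
    class = "assay_truth"
  )
}

#' Preset assay truths
#'
#' `"cypa"` and `"cypb"`: cyclophilin-like PPIases with no sequence
#' preference (one kcat/KM for all five peptides, 3e6 and 8e6 M^-1 s^-1
#' respectively). `"slyd"`: an FKBP-like enzyme with pronounced sequence
#' specificity (kcat/KM spanning two orders of magnitude across the Xaa
#' positions). Uncatalyzed rates default to 0.02 s^-1, an
#' order-of-magnitude choice for Xaa-Pro peptides at 15 °C.
#'
#' @param preset `"cypa"`, `"cypb"` or `"slyd"`.
#' @param ... Overrides passed to [assay_truth()].
#' @export
assay_preset <- function(preset = c("cypa", "cypb", "slyd"), ...) {
  preset <- match.arg(preset)
  base <- switch(
    preset,
    cypa = list(kcat_over_KM_M_s = 3e6),
    cypb = list(kcat_over_KM_M_s = 8e6),
    slyd = list(kcat_over_KM_M_s = c(AAPF = 1e5, AEPF = 3e4, AKPF = 1e5,
                                     ALPF = 5e6, AYPF = 2e6))
  )
  do.call(assay_truth, utils::modifyList(base, list(...)))
}

#' Generate one synthetic kinetic trace
#'
#' Forward model
#' \deqn{I(t) = I_\infty - A\,e^{-(k_0 + [E] k_{cat}/K_M)\,t}
#'   - A_{slow}\,e^{-k_{slow} t} + \epsilon(t),}
#' sampled every `dt_s` seconds from 0 to `duration_s`, with
#' multiplicative Gaussian noise (relative scale) by default.
#'
#' @param truth An `assay_truth`.
#' @param peptide_id One of `truth$peptides`.
#' @param enzyme_concentration_M Enzyme concentration (mol/L).
#' @param seed Integer seed.
#' @param replicate_id Replicate label.
#' @param noise_model `"multiplicative"` or `"additive"`.
#' @return A `kinetic_trace` with attribute `truth` holding the
#'   generating rate and parameters.
#' @export
generate_trace <- function(truth, peptide_id, enzyme_concentration_M,
                           seed = 1L, replicate_id = "sim1",
                           noise_model = c("multiplicative", "additive")) {
  stopifnot(inherits(truth, "assay_truth"),
            peptide_id %in% truth$peptides)
  noise_model <- match.arg(noise_model)
  t <- seq(0, truth$duration_s, by = truth$dt_s)
  kapp <- truth$k0_s[[peptide_id]] +
    enzyme_concentration_M * truth$kcat_over_KM_M_s[[peptide_id]]
  mu <- truth$offset - truth$amplitude * exp(-kapp * t)
  if (!is.null(truth$slow_phase)) {
    mu <- mu - truth$slow_phase$amplitude_fraction * truth$amplitude *
      exp(-truth$slow_phase$rate_s * t)
  }
  y <- with_seed(seed, {
    if (truth$noise_relative == 0) {
      mu
    } else if (noise_model == "multiplicative") {
      mu * (1 + stats::rnorm(length(mu), 0, truth$noise_relative))
    } else {
      mu + stats::rnorm(length(mu), 0, truth$noise_relative * truth$offset)
    }
  })
  tr <- kinetic_trace(t, y, enzyme_concentration_M = enzyme_concentration_M,
                      peptide_id = peptide_id, condition = truth$condition,
                      temperature_K = truth$temperature_K,
                      replicate_id = replicate_id)
  attr(tr, "truth") <- list(kapp_s = unname(kapp),
                            k0_s = truth$k0_s[[peptide_id]],
                            kcat_over_KM_M_s =
                              truth$kcat_over_KM_M_s[[peptide_id]],
                            slow_phase = truth$slow_phase, seed = seed)
  tr
}

#' Generate a full factorial synthetic assay
#'
#' Peptide x concentration x replicate trace set. Per-trace seeds are
#' derived deterministically from the master seed and the (peptide,
#' concentration, replicate) indices through a fixed integer mixing rule
#' (see `child_seed()` in the package source), so any single trace can
#' be regenerated in isolation.
#'
#' @param truth An `assay_truth` with >= 3 concentrations including 0
#'   and >= 1 replicate.
#' @param seed Master seed.
#' @param noise_model Passed to [generate_trace()].
#' @return List of `kinetic_trace` objects with attribute `truth` (the
#'   generating `assay_truth` plus master seed).
#' @export
generate_assay <- function(truth, seed = 1L,
                           noise_model = c("multiplicative", "additive")) {
  stopifnot(inherits(truth, "assay_truth"))
  noise_model <- match.arg(noise_model)
  if (length(unique(truth$enzyme_concentrations_M)) < 3L ||
      !any(truth$enzyme_concentrations_M == 0)) {
    abort("assay design needs >= 3 concentrations including 0",
          "cyclofit_validation_error")
  }
  if (truth$n_replicates < 1L) {
    abort("assay design needs >= 1 replicate per concentration",
          "cyclofit_validation_error")
  }
  traces <- list()
  for (pi in seq_along(truth$peptides)) {
    for (ci in seq_along(truth$enzyme_concentrations_M)) {
      for (ri in seq_len(truth$n_replicates)) {
        s <- child_seed(seed, pi, ci, ri)
        tr <- generate_trace(
          truth, truth$peptides[pi], truth$enzyme_concentrations_M[ci],
          seed = s, replicate_id = sprintf("rep%d", ri),
          noise_model = noise_model
        )
        traces[[length(traces) + 1L]] <- tr
      }
    }
  }
  attr(traces, "truth") <- c(unclass(truth),
                             list(master_seed = seed,
                                  noise_model = noise_model))
  traces
}

#' Final concentration after an assay dilution
#'
#' `c_final = c_stock * v_stock / v_final`, e.g. 5 uL of a 750 uM
#' peptide stock into a 1000 uL assay gives 3.75 uM.
#'
#' @param stock_volume_uL Volume of stock added (uL).
#' @param stock_concentration_uM Stock concentration (uM).
#' @param final_volume_uL Total assay volume (uL).
#' @return Final concentration in uM.
#' @export
#' @examples
#' assay_concentration(5, 750, 1000)  # 3.75
assay_concentration <- function(stock_volume_uL, stock_concentration_uM,
                                final_volume_uL) {
  check_positive_scalar(stock_volume_uL, "stock_volume_uL")
  check_positive_scalar(stock_concentration_uM, "stock_concentration_uM")
  check_positive_scalar(final_volume_uL, "final_volume_uL")
  if (stock_volume_uL > final_volume_uL) {
    abort("stock volume cannot exceed the final volume",
          "cyclofit_validation_error")
  }
  stock_concentration_uM * stock_volume_uL / final_volume_uL
}
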