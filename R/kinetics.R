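# Isomerization kinetics: exponential decomposition of fluorescence
# relaxation traces, model selection, identification of the
# PPIase-sensitive phase, replicate averaging, and the specificity-
# constant regression k_app = k0 + [E] * kcat/KM.

#' Construct a kinetic trace
#'
#' One fluorescence time course of a peptidyl-prolyl cis/trans
#' re-equilibration after solvent jump, recorded at a known PPIase
#' concentration. Time zero is the mixing dead-time origin (peptide
#' addition).
#'
#' @param time_s Strictly increasing sampling times (s), starting at 0.
#' @param intensity Fluorescence intensity (arbitrary units).
#' @param enzyme_concentration_M PPIase concentration (mol/L, >= 0).
#' @param peptide_id Tetrapeptide identifier, e.g. `"AAPF"`, `"AEPF"`,
#'   `"AKPF"`, `"ALPF"`, `"AYPF"` (Ala-Xaa-Pro-Phe naming).
#' @param condition `"reducing"` (cytosol-mimicking, DTT) or
#'   `"er_mimicking"` (GSH/GSSG + Ca2+). Metadata only; it never enters
#'   any numeric computation.
#' @param temperature_K Absolute temperature; defaults to 288.15 K.
#' @param replicate_id Replicate identifier.
#' @return An object of class `kinetic_trace`.
#' @export
kinetic_trace <- function(time_s, intensity, enzyme_concentration_M = 0,
                          peptide_id = "AAPF",
                          condition = c("reducing", "er_mimicking"),
                          temperature_K = 288.15, replicate_id = "r1") {
  condition <- match.arg(condition)
  time_s <- as.numeric(time_s)
  intensity <- as.numeric(intensity)
  if (length(time_s) != length(intensity)) {
    abort("time and intensity must have equal length",
          "cyclofit_validation_error")
  }
  if (length(time_s) < 20L) {
    abort("a kinetic trace needs >= 20 samples", "cyclofit_validation_error")
  }
  if (any(diff(time_s) <= 0) || time_s[1] < 0) {
    abort("time must be strictly increasing from the t = 0 origin",
          "cyclofit_validation_error")
  }
  if (!is_scalar_number(enzyme_concentration_M) ||
      enzyme_concentration_M < 0) {
    abort("enzyme concentration must be a non-negative number (mol/L)",
          "cyclofit_validation_error")
  }
  structure(
    list(time_s = time_s, intensity = intensity,
         enzyme_concentration_M = enzyme_concentration_M,
         peptide_id = peptide_id, condition = condition,
         temperature_K = temperature_K, replicate_id = replicate_id),
    class = "kinetic_trace"
  )
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat(sprintf(
    "<kinetic_trace %s/%s %s: %d points, 0-%.0f s, [E] = %.3g M>\n",
    x$peptide_id, x$condition, x$replicate_id, length(x$time_s),
    max(x$time_s), x$enzyme_concentration_M))
  invisible(x)
}

# Rate starting guess from the time at which the trace has covered
# 1 - 1/e of its total amplitude.
rate_guess <- function(t, y) {
  y0 <- y[1]
  yinf <- mean(utils::tail(y, max(3L, length(y) %/% 10L)))
  if (abs(yinf - y0) < .Machine$double.eps) return(0.05)
  frac <- (y - y0) / (yinf - y0)
  idx <- which(frac >= 1 - exp(-1))[1]
  if (is.na(idx) || t[idx] <= 0) return(1 / max(t) * 3)
  1 / t[idx]
}

exp_model <- function(t, offset, amps, rates) {
  out <- rep(offset, length(t))
  for (i in seq_along(amps)) out <- out - amps[i] * exp(-rates[i] * t)
  out
}

#' Fit an exponential relaxation model to a kinetic trace
#'
#' Least-squares fit of
#' \deqn{I(t) = I_\infty - \sum_i A_i e^{-k_i t},}
#' so a rising fluorescence trace has positive amplitudes. Rates are
#' fitted on a log scale to enforce positivity and returned sorted in
#' descending order. Starting rates come from the trace's 1 - 1/e
#' crossing time; up to `restarts` seeded multi-start attempts with
#' jittered starts guard against local minima. The first `dead_time_s`
#' seconds are excluded by default to discard the manual-mixing
#' artifact.
#'
#' @param trace A `kinetic_trace`.
#' @param n_phases 1 or 2 exponential phases.
#' @param dead_time_s Initial portion of the trace to exclude (s).
#' @param restarts Jittered restarts after the data-driven start.
#' @param jitter_seed Seed for restart jitter.
#' @return An object of class `kinetic_fit`: `n_phases`, `rates_s`
#'   (descending), `amplitudes` (matching order), `offset`,
#'   `residual_sd`, `rss`, `n_obs`, `aicc`, `enzyme_concentration_M`,
#'   `peptide_id`, `condition`, `replicate_id`,
#'   `enzyme_sensitive_phase` (`NA` until assigned).
#' @export
fit_exponential <- function(trace, n_phases = 1L, dead_time_s = 2,
                            restarts = 3L, jitter_seed = 1L) {
  stopifnot(inherits(trace, "kinetic_trace"), n_phases %in% c(1L, 2L))
  n_phases <- as.integer(n_phases)
  keep <- trace$time_s >= dead_time_s
  t <- trace$time_s[keep]
  y <- trace$intensity[keep]
  if (length(t) < 10L + 2L * n_phases) {
    abort("too few points after dead-time exclusion",
          "cyclofit_validation_error")
  }

  # flat trace: amplitude indistinguishable from point-to-point noise
  noise_hat <- stats::sd(diff(y)) / sqrt(2)
  if (stats::sd(y) == 0 || diff(range(y)) < 4 * noise_hat) {
    abort("no relaxation signal detectable beyond noise",
          "cyclofit_no_signal_error")
  }

  k0 <- rate_guess(t, y)
  offset0 <- mean(utils::tail(y, max(3L, length(y) %/% 10L)))
  amp_tot <- offset0 - y[1]
  df <- data.frame(t = t, y = y)

  make_start <- function(fac_k, fac_a) {
    if (n_phases == 1L) {
      list(lk1 = log(k0 * fac_k[1]), a1 = amp_tot * fac_a[1],
           off = offset0)
    } else {
      list(lk1 = log(k0 * 4 * fac_k[1]), lk2 = log(k0 / 4 * fac_k[2]),
           a1 = amp_tot / 2 * fac_a[1], a2 = amp_tot / 2 * fac_a[2],
           off = offset0)
    }
  }
  starts <- list(make_start(c(1, 1), c(1, 1)))
  if (restarts > 0) {
    jit <- with_seed(jitter_seed, {
      lapply(seq_len(restarts), function(i) {
        make_start(stats::runif(2, 0.5, 2), stats::runif(2, 0.7, 1.3))
      })
    })
    starts <- c(starts, jit)
  }

  formula <- if (n_phases == 1L) {
    y ~ off - a1 * exp(-exp(lk1) * t)
  } else {
    y ~ off - a1 * exp(-exp(lk1) * t) - a2 * exp(-exp(lk2) * t)
  }

  best <- NULL
  for (st in starts) {
    best <- tryCatch(
      minpack.lm::nlsLM(formula, data = df, start = st,
                        control = minpack.lm::nls.lm.control(
                          maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL
    )
    if (!is.null(best)) break
  }
  if (is.null(best)) {
    abort("exponential fit failed to converge after restarts",
          "cyclofit_convergence_error")
  }

  best_rss <- sum(stats::residuals(best)^2)
  p <- stats::coef(best)
  if (n_phases == 1L) {
    rates <- exp(p[["lk1"]])
    amps <- p[["a1"]]
  } else {
    rates <- exp(c(p[["lk1"]], p[["lk2"]]))
    amps <- c(p[["a1"]], p[["a2"]])
    ord <- order(rates, decreasing = TRUE)
    rates <- rates[ord]
    amps <- amps[ord]
  }
  n <- length(t)
  npar <- 2L * n_phases + 1L
  # Gaussian log-likelihood AIC with small-sample correction
  aic <- n * log(best_rss / n) + 2 * (npar + 1)
  aicc <- aic + 2 * (npar + 1) * (npar + 2) / max(1, n - npar - 2)

  structure(
    list(n_phases = n_phases, rates_s = unname(rates),
         amplitudes = unname(amps), offset = unname(p[["off"]]),
         residual_sd = sqrt(best_rss / max(1L, n - npar)),
         rss = best_rss, n_obs = n, aicc = aicc,
         enzyme_concentration_M = trace$enzyme_concentration_M,
         peptide_id = trace$peptide_id, condition = trace$condition,
         replicate_id = trace$replicate_id,
         enzyme_sensitive_phase = NA_integer_),
    class = "kinetic_fit"
  )
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit %s [E]=%.3g M: %d phase(s), rate(s) %s s^-1>\n",
              x$peptide_id, x$enzyme_concentration_M, x$n_phases,
              paste(signif(x$rates_s, 4), collapse = ", ")))
  invisible(x)
}

#' Choose between one and two exponential phases
#'
#' Fits both models and returns 2 only when the two-phase fit wins the
#' corrected Akaike information criterion *and* passes the resolvability
#' gates: rate ratio >= `min_rate_ratio` and minor-phase amplitude at
#' least `min_amplitude_fraction` of the total. The gates keep noise
#' from being promoted to a phase.
#'
#' @param trace A `kinetic_trace`.
#' @param min_rate_ratio Minimum fast/slow rate ratio for a resolvable
#'   second phase (default 5).
#' @param min_amplitude_fraction Minimum minor-phase share of the total
#'   amplitude (default 0.10).
#' @param ... Passed to [fit_exponential()].
#' @return List with elements `n_phases` (1 or 2), `fit` (the selected
#'   `kinetic_fit`), `fit1`, `fit2` (may be `NULL` if the 2-phase fit
#'   failed), `delta_aicc`.
#' @export
select_model <- function(trace, min_rate_ratio = 5,
                         min_amplitude_fraction = 0.10, ...) {
  fit1 <- fit_exponential(trace, n_phases = 1L, ...)
  fit2 <- tryCatch(fit_exponential(trace, n_phases = 2L, ...),
                   error = function(e) NULL)
  choose2 <- FALSE
  delta <- NA_real_
  if (!is.null(fit2)) {
    delta <- fit1$aicc - fit2$aicc
    ratio <- fit2$rates_s[1] / fit2$rates_s[2]
    amp_frac <- min(abs(fit2$amplitudes)) / sum(abs(fit2$amplitudes))
    choose2 <- delta > 0 && ratio >= min_rate_ratio &&
      amp_frac >= min_amplitude_fraction &&
      all(fit2$amplitudes > 0)
  }
  list(n_phases = if (choose2) 2L else 1L,
       fit = if (choose2) fit2 else fit1,
       fit1 = fit1, fit2 = fit2, delta_aicc = delta)
}

#' Identify the PPIase-sensitive phase across enzyme concentrations
#'
#' For traces that resolve two phases, the catalyzed isomerization is the
#' phase whose rate increases linearly with enzyme concentration while
#' the contaminant phase stays flat. Each phase's rates (fast = largest
#' rate per fit, slow = second) are regressed on \[E\]; the flagged phase
#' must have a statistically positive slope (one-sided p <
#' `alpha`) and the larger slope of the two, and the other phase's slope
#' must be compatible with zero. If both phases are concentration-
#' dependent the assignment is ambiguous and an error is raised rather
#' than a silent choice.
#'
#' @param fits List of `kinetic_fit` objects spanning >= 3 distinct
#'   enzyme concentrations including 0.
#' @param alpha Significance level for the slope tests (default 0.05).
#' @return The input list with `enzyme_sensitive_phase` set on each fit
#'   (1 = fastest phase), plus attribute `phase_slopes` summarizing the
#'   per-phase regressions.
#' @export
identify_enzyme_sensitive_phase <- function(fits, alpha = 0.05) {
  stopifnot(all(vapply(fits, inherits, logical(1), "kinetic_fit")))
  conc <- vapply(fits, `[[`, numeric(1), "enzyme_concentration_M")
  if (length(unique(conc)) < 3L || !any(conc == 0)) {
    abort("need fits at >= 3 distinct enzyme concentrations including 0",
          "cyclofit_insufficient_design_error")
  }
  nph <- vapply(fits, `[[`, integer(1), "n_phases")
  if (all(nph == 1L)) {
    for (i in seq_along(fits)) fits[[i]]$enzyme_sensitive_phase <- 1L
    attr(fits, "phase_slopes") <- NULL
    return(fits)
  }

  # phase 1 = fastest rate in every fit; phase 2 = slow rate where resolved
  fast <- vapply(fits, function(f) f$rates_s[1], numeric(1))
  slow <- vapply(fits, function(f) {
    if (f$n_phases == 2L) f$rates_s[2] else NA_real_
  }, numeric(1))

  slope_test <- function(k, E) {
    ok <- is.finite(k)
    if (sum(ok) < 3L) return(list(slope = NA_real_, p_pos = NA_real_))
    m <- stats::lm(k[ok] ~ E[ok])
    # summary.lm warns on residual-free (noiseless) data; harmless here
    sm <- suppressWarnings(summary(m))$coefficients
    tval <- sm[2, "t value"]
    list(slope = sm[2, "Estimate"],
         p_pos = stats::pt(tval, df = m$df.residual, lower.tail = FALSE))
  }
  ts_fast <- slope_test(fast, conc)
  ts_slow <- slope_test(slow, conc)

  fast_dep <- !is.na(ts_fast$p_pos) && ts_fast$p_pos < alpha
  slow_dep <- !is.na(ts_slow$p_pos) && ts_slow$p_pos < alpha

  if (fast_dep && slow_dep) {
    abort("both phases depend on enzyme concentration; assignment ambiguous",
          "cyclofit_ambiguity_error")
  }
  if (!fast_dep && slow_dep) {
    abort("only the slow phase tracks enzyme concentration; check phase ordering",
          "cyclofit_ambiguity_error")
  }
  for (i in seq_along(fits)) fits[[i]]$enzyme_sensitive_phase <- 1L
  attr(fits, "phase_slopes") <- data.frame(
    phase = c("fast", "slow"),
    slope = c(ts_fast$slope, ts_slow$slope),
    p_positive = c(ts_fast$p_pos, ts_slow$p_pos)
  )
  fits
}

#' Average PPIase-sensitive rates per enzyme concentration
#'
#' Arithmetic mean and sample SD of the flagged-phase rates across
#' replicates at each enzyme concentration. With a single replicate the
#' mean is that value and the SD is reported as `NA`.
#'
#' @param fits List of `kinetic_fit` objects with
#'   `enzyme_sensitive_phase` assigned (see
#'   [identify_enzyme_sensitive_phase()]).
#' @return `data.frame` with columns `enzyme_concentration_M`,
#'   `mean_kapp_s`, `sd_kapp_s`, `n`.
#' @export
average_rates <- function(fits) {
  stopifnot(all(vapply(fits, inherits, logical(1), "kinetic_fit")))
  phase <- vapply(fits, `[[`, integer(1), "enzyme_sensitive_phase")
  if (anyNA(phase)) {
    abort("enzyme-sensitive phase not assigned; run identify_enzyme_sensitive_phase()",
          "cyclofit_validation_error")
  }
  conc <- vapply(fits, `[[`, numeric(1), "enzyme_concentration_M")
  k <- mapply(function(f, ph) f$rates_s[ph], fits, phase)
  agg <- split(k, conc)
  out <- data.frame(
    enzyme_concentration_M = as.numeric(names(agg)),
    mean_kapp_s = vapply(agg, mean, numeric(1)),
    sd_kapp_s = vapply(agg, function(v) {
      if (length(v) >= 2L) stats::sd(v) else NA_real_
    }, numeric(1)),
    n = vapply(agg, length, integer(1)),
    row.names = NULL
  )
  out[order(out$enzyme_concentration_M), ]
}

#' Specificity constant from the rate-versus-concentration regression
#'
#' Ordinary least-squares line through the per-concentration mean
#' apparent rates,
#' \deqn{k_{app} = k_0 + [E] \cdot k_{cat}/K_M,}
#' so the slope is the specificity constant kcat/KM (M^-1 s^-1) and the
#' intercept the uncatalyzed re-equilibration rate k0 (s^-1). The
#' regression is unweighted by default; `weighted = TRUE` uses 1/SD^2
#' weights for sensitivity analysis.
#'
#' @param points `data.frame` as returned by [average_rates()]; needs >=
#'   3 concentrations including \[E\] = 0, in molar.
#' @param peptide_id,condition Labels copied into the result.
#' @param weighted Use inverse-variance weights (requires finite SDs).
#' @return An object of class `specificity_result`: `peptide_id`,
#'   `condition`, `k0_s` and `k0_sd`, `kcat_over_KM_M_s` and
#'   `kcat_over_KM_sd`, `n_points`, `accepted` (FALSE for a negative
#'   fitted slope), `points` (the input averages).
#' @export
fit_specificity <- function(points, peptide_id = NA_character_,
                            condition = NA_character_, weighted = FALSE) {
  stopifnot(is.data.frame(points),
            all(c("enzyme_concentration_M", "mean_kapp_s") %in%
                  names(points)))
  E <- points$enzyme_concentration_M
  k <- points$mean_kapp_s
  if (length(unique(E)) < 3L || !any(E == 0)) {
    abort("specificity regression needs >= 3 concentrations including [E] = 0",
          "cyclofit_insufficient_design_error")
  }
  w <- NULL
  if (weighted) {
    sds <- points$sd_kapp_s
    if (is.null(sds) || anyNA(sds) || any(sds <= 0)) {
      abort("weighted regression requires positive SDs at every concentration",
            "cyclofit_validation_error")
    }
    w <- 1 / sds^2
  }
  m <- stats::lm(k ~ E, weights = w)
  sm <- suppressWarnings(summary(m))$coefficients
  slope <- unname(sm["E", "Estimate"])
  structure(
    list(peptide_id = peptide_id, condition = condition,
         k0_s = unname(sm["(Intercept)", "Estimate"]),
         k0_sd = unname(sm["(Intercept)", "Std. Error"]),
         kcat_over_KM_M_s = slope,
         kcat_over_KM_sd = unname(sm["E", "Std. Error"]),
         n_points = length(E),
         accepted = slope >= 0,
         points = points),
    class = "specificity_result"
  )
}

#' @export
print.specificity_result <- function(x, ...) {
  cat(sprintf(
    "<specificity_result %s/%s: kcat/KM = %.3g +/- %.2g M^-1 s^-1, k0 = %.3g +/- %.2g s^-1%s>\n",
    x$peptide_id, x$condition, x$kcat_over_KM_M_s, x$kcat_over_KM_sd,
    x$k0_s, x$k0_sd, if (x$accepted) "" else " [not accepted]"))
  invisible(x)
}

#' Read / write a kinetic trace as delimited text
#'
#' Columns (time_s, intensity) with `# key=value` metadata including
#' `enzyme_concentration_nM`, `peptide_id`, `condition`,
#' `temperature_C`, `replicate_id`. Enzyme concentrations are stored in
#' nM in the file and carried in molar in memory.
#'
#' @param path File path.
#' @return `read_trace()` returns a `kinetic_trace`.
#' @export
read_trace <- function(path) {
  raw <- read_xy_file(path)
  conc_nM <- raw$meta$enzyme_concentration_nM %||% 0
  tempC <- raw$meta$temperature_C %||% 15
  kinetic_trace(raw$x, raw$y,
                enzyme_concentration_M = conc_nM * 1e-9,
                peptide_id = raw$meta$peptide_id %||% "AAPF",
                condition = raw$meta$condition %||% "reducing",
                temperature_K = tempC + 273.15,
                replicate_id = raw$meta$replicate_id %||% basename(path))
}

#' @rdname read_trace
#' @param trace A `kinetic_trace` to serialize.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "kinetic_trace"))
  write_xy_file(
    path, trace$time_s, trace$intensity,
    meta = list(enzyme_concentration_nM = trace$enzyme_concentration_M * 1e9,
                peptide_id = trace$peptide_id,
                condition = trace$condition,
                temperature_C = trace$temperature_K - 273.15,
                replicate_id = trace$replicate_id),
    columns = c("time_s", "intensity")
  )
}
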