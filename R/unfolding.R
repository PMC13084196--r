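# Equilibrium urea-unfolding analysis: refractive-index calibration,
# two-state linear-extrapolation model, nonlinear fitting with multistart
# restarts, and replicate aggregation.

#' Pace calibration for urea concentration from refractive index
#'
#' Cubic polynomial in the refractive-index difference between a
#' urea-containing sample and its buffer,
#' \deqn{[urea] = 117.66\,\Delta N + 29.753\,\Delta N^2 + 185.56\,\Delta N^3,}
#' the standard calibration for urea at 25 °C. The coefficients are
#' exposed as an argument so an alternative calibration record can be
#' substituted.
#'
#' @param n_sample Refractive index of the sample (1.3-1.5).
#' @param n_buffer Refractive index of the matched buffer.
#' @param coefficients Cubic coefficients, lowest order first.
#' @return Urea concentration in mol/L.
#' @export
#' @examples
#' urea_from_refractive_index(1.3480, 1.3330)  # ~1.77 M
urea_from_refractive_index <- function(n_sample, n_buffer,
                                       coefficients = c(117.66, 29.753,
                                                        185.56)) {
  if (any(n_sample < 1.3 | n_sample > 1.5) ||
      any(n_buffer < 1.3 | n_buffer > 1.5)) {
    abort("refractive indices must lie in the physically plausible 1.3-1.5",
          "cyclofit_validation_error")
  }
  dn <- n_sample - n_buffer
  if (any(dn < 0)) {
    abort("sample refractive index below buffer (negative ΔN)",
          "cyclofit_validation_error")
  }
  urea <- coefficients[1] * dn + coefficients[2] * dn^2 +
    coefficients[3] * dn^3
  if (any(urea > 11)) {
    abort("computed urea exceeds the 0-11 M calibration range",
          "cyclofit_calibration_error")
  }
  urea
}

#' Construct an unfolding dataset
#'
#' One replicate of a denaturant titration: (urea, signal) pairs recorded
#' at a fixed temperature, optionally with a protein-free blank series
#' for buffer-fluorescence correction.
#'
#' @param urea_M Non-negative urea concentrations (M).
#' @param signal Fluorescence signal at each urea concentration (a.u.).
#' @param temperature_K Absolute temperature; defaults to 288.15 K (15 °C).
#' @param replicate_id Identifier for the replicate.
#' @param blank_series Optional `data.frame` with columns `urea_M`,
#'   `signal` from a protein-free titration.
#' @return An object of class `unfolding_dataset`.
#' @export
unfolding_dataset <- function(urea_M, signal, temperature_K = 288.15,
                              replicate_id = "r1", blank_series = NULL) {
  urea_M <- as.numeric(urea_M)
  signal <- as.numeric(signal)
  if (length(urea_M) != length(signal)) {
    abort("urea and signal must have equal length",
          "cyclofit_validation_error")
  }
  if (any(!is.finite(urea_M)) || any(urea_M < 0)) {
    abort("urea concentrations must be finite and non-negative",
          "cyclofit_validation_error")
  }
  if (anyDuplicated(urea_M)) {
    abort("at most one signal per urea concentration within a replicate",
          "cyclofit_validation_error")
  }
  check_positive_scalar(temperature_K, "temperature_K")
  ord <- order(urea_M)
  structure(
    list(urea_M = urea_M[ord], signal = signal[ord],
         temperature_K = temperature_K, replicate_id = replicate_id,
         blank_series = blank_series),
    class = "unfolding_dataset"
  )
}

#' @export
print.unfolding_dataset <- function(x, ...) {
  cat(sprintf("<unfolding_dataset %s: %d points, %.2f-%.2f M urea, %.2f K>\n",
              x$replicate_id, length(x$urea_M), min(x$urea_M),
              max(x$urea_M), x$temperature_K))
  invisible(x)
}

fit_eligible <- function(data) {
  length(data$urea_M) >= 8L && diff(range(data$urea_M)) >= 2
}

#' Two-state linear-extrapolation signal model
#'
#' Expected observable of a two-state unfolding transition with linearly
#' sloping native and unfolded baselines:
#' \deqn{y(D) = \frac{(y_N^0 + m_N D) + (y_U^0 + m_U D)\,
#'   e^{-\Delta G/RT + m D/RT}}{1 + e^{-\Delta G/RT + m D/RT}}}
#' with R = 8.314e-3 kJ mol^-1 K^-1.
#'
#' @param urea_M Denaturant concentration(s) D (M).
#' @param yN0,mN Native baseline intercept and slope.
#' @param yU0,mU Unfolded baseline intercept and slope.
#' @param dG_kJ_mol Free energy of unfolding at 0 M urea (kJ/mol).
#' @param m_kJ_mol_M Cooperativity parameter (kJ mol^-1 M^-1).
#' @param temperature_K Absolute temperature (K).
#' @return Expected signal at each `urea_M`.
#' @export
two_state_signal <- function(urea_M, yN0, mN, yU0, mU, dG_kJ_mol,
                             m_kJ_mol_M, temperature_K = 288.15) {
  check_positive_scalar(temperature_K, "temperature_K")
  RT <- R_GAS_KJ * temperature_K
  K <- exp(-dG_kJ_mol / RT + m_kJ_mol_M * urea_M / RT)
  ((yN0 + mN * urea_M) + (yU0 + mU * urea_M) * K) / (1 + K)
}

#' Fraction of unfolded protein under the two-state model
#'
#' \eqn{f_U = K/(1+K)} with \eqn{K = e^{-\Delta G/RT + m D/RT}}; strictly
#' increasing in denaturant for m > 0 and exactly 0.5 at the midpoint
#' D = \eqn{\Delta G / m}.
#'
#' @inheritParams two_state_signal
#' @return Fraction unfolded in \[0, 1\].
#' @export
fraction_unfolded <- function(urea_M, dG_kJ_mol, m_kJ_mol_M,
                              temperature_K = 288.15) {
  check_positive_scalar(temperature_K, "temperature_K")
  RT <- R_GAS_KJ * temperature_K
  K <- exp(-dG_kJ_mol / RT + m_kJ_mol_M * urea_M / RT)
  K / (1 + K)
}

#' Linearly interpolate a blank titration at arbitrary urea
#'
#' Protein-free blanks are recorded on a coarse urea grid (1 M steps);
#' the correction at a sample's urea concentration is the linear
#' interpolation between the two bracketing blank measurements.
#' Extrapolation beyond the blank range is refused.
#'
#' @param blank_series `data.frame` with columns `urea_M`, `signal`.
#' @param urea_M Query concentration(s).
#' @return Interpolated blank signal at each query point.
#' @export
blank_interpolate <- function(blank_series, urea_M) {
  stopifnot(is.data.frame(blank_series),
            all(c("urea_M", "signal") %in% names(blank_series)))
  rng <- range(blank_series$urea_M)
  if (any(urea_M < rng[1] | urea_M > rng[2])) {
    abort(sprintf("query outside blank range [%.3g, %.3g] M",
                  rng[1], rng[2]),
          "cyclofit_extrapolation_error")
  }
  stats::approx(blank_series$urea_M, blank_series$signal, xout = urea_M,
                method = "linear", ties = "ordered")$y
}

# Data-driven starting values: baselines by OLS on the lowest/highest 20%
# of urea points; midpoint guess at the urea of maximum |finite-difference
# derivative|; m at 5 kJ/mol/M; dG = m * midpoint guess.
two_state_start <- function(data) {
  D <- data$urea_M
  y <- data$signal
  n <- length(D)
  k <- max(2L, ceiling(0.2 * n))
  lo <- seq_len(k)
  hi <- seq.int(n - k + 1L, n)
  cn <- stats::coef(stats::lm(y[lo] ~ D[lo]))
  cu <- stats::coef(stats::lm(y[hi] ~ D[hi]))
  dy <- diff(y) / diff(D)
  mid_guess <- ((D[-1] + D[-n]) / 2)[which.max(abs(dy))]  # segment center
  m0 <- 5
  list(yN0 = unname(cn[1]), mN = unname(cn[2]),
       yU0 = unname(cu[1]), mU = unname(cu[2]),
       dG = m0 * mid_guess, m = m0)
}

#' Fit the two-state unfolding model to a titration
#'
#' Unweighted Levenberg-Marquardt least squares on the six parameters of
#' the linear-extrapolation model. Starting values are derived from the
#' data; on failure to converge, up to `restarts` additional attempts are
#' made from seeded +/-20% jittered starts. A fit is *accepted* only if
#' it converged with m > 0, dG > 0 and a transition midpoint (dG/m,
#' always recomputed, never stored independently) inside the sampled urea
#' range — baseline-only data cannot yield spurious thermodynamics.
#'
#' @param data An `unfolding_dataset`. If it carries a `blank_series` the
#'   interpolated blank is subtracted before fitting.
#' @param restarts Number of jittered restarts after the data-driven
#'   start (default 5).
#' @param jitter_seed Seed for the restart jitter.
#' @param gates Named list overriding acceptance gates: `require_m_pos`,
#'   `require_dG_pos`, `require_midpoint_in_range` (all `TRUE` by
#'   default).
#' @return An object of class `two_state_fit` with elements `yN0`, `mN`,
#'   `yU0`, `mU`, `dG_kJ_mol`, `m_kJ_mol_M`, `midpoint_M`, `covariance`,
#'   `residual_sd`, `converged`, `accepted`, `reject_reason`,
#'   `temperature_K`, `replicate_id`.
#' @export
fit_two_state <- function(data, restarts = 5L, jitter_seed = 1L,
                          gates = list()) {
  stopifnot(inherits(data, "unfolding_dataset"))
  if (!fit_eligible(data)) {
    abort("dataset not fit-eligible: need >= 8 points spanning >= 2 M urea",
          "cyclofit_validation_error")
  }
  y <- data$signal
  if (!is.null(data$blank_series)) {
    y <- y - blank_interpolate(data$blank_series, data$urea_M)
  }
  D <- data$urea_M
  Tk <- data$temperature_K

  # degenerate data: total signal change indistinguishable from the
  # point-to-point scatter (noise estimated from successive differences)
  noise_hat <- stats::sd(diff(y)) / sqrt(2)
  if (stats::sd(y) == 0 || diff(range(y)) < 4 * noise_hat) {
    abort("no unfolding transition detectable beyond noise",
          "cyclofit_no_transition_error")
  }

  df <- data.frame(D = D, y = y)
  start0 <- two_state_start(data)
  starts <- list(start0)
  if (restarts > 0) {
    jit <- with_seed(jitter_seed, {
      lapply(seq_len(restarts), function(i) {
        lapply(start0, function(p) p * stats::runif(1, 0.8, 1.2))
      })
    })
    starts <- c(starts, jit)
  }

  best <- NULL
  for (st in starts) {
    best <- tryCatch(
      minpack.lm::nlsLM(
        y ~ two_state_signal(D, yN0, mN, yU0, mU, dG, m, Tk),
        data = df, start = st,
        control = minpack.lm::nls.lm.control(maxiter = 500,
                                             ftol = 1e-14, ptol = 1e-14)
      ),
      error = function(e) NULL
    )
    if (!is.null(best)) break
  }
  if (is.null(best)) {
    abort("two-state fit failed to converge after restarts",
          "cyclofit_convergence_error")
  }

  best_rss <- sum(stats::residuals(best)^2)
  p <- stats::coef(best)
  covmat <- tryCatch(stats::vcov(best), error = function(e) {
    matrix(NA_real_, 6, 6)
  })
  midpoint <- unname(p["dG"] / p["m"])
  gate <- utils::modifyList(
    list(require_m_pos = TRUE, require_dG_pos = TRUE,
         require_midpoint_in_range = TRUE),
    gates
  )
  reject <- character(0)
  if (gate$require_m_pos && p["m"] <= 0) reject <- c(reject, "m_not_positive")
  if (gate$require_dG_pos && p["dG"] <= 0) reject <- c(reject, "dG_not_positive")
  if (gate$require_midpoint_in_range &&
      (midpoint < min(D) || midpoint > max(D))) {
    reject <- c(reject, "midpoint_outside_sampled_range")
  }

  structure(
    list(yN0 = unname(p["yN0"]), mN = unname(p["mN"]),
         yU0 = unname(p["yU0"]), mU = unname(p["mU"]),
         dG_kJ_mol = unname(p["dG"]), m_kJ_mol_M = unname(p["m"]),
         midpoint_M = midpoint,
         covariance = covmat,
         residual_sd = sqrt(best_rss / max(1L, length(D) - 6L)),
         converged = TRUE,
         accepted = length(reject) == 0L,
         reject_reason = reject,
         temperature_K = Tk,
         replicate_id = data$replicate_id),
    class = "two_state_fit"
  )
}

#' @export
print.two_state_fit <- function(x, ...) {
  cat(sprintf(
    "<two_state_fit %s: dG = %.2f kJ/mol, m = %.2f kJ/mol/M, midpoint = %.3f M%s>\n",
    x$replicate_id, x$dG_kJ_mol, x$m_kJ_mol_M, x$midpoint_M,
    if (x$accepted) "" else paste0(" [rejected: ",
                                   paste(x$reject_reason, collapse = ","), "]")
  ))
  invisible(x)
}

#' Aggregate replicate two-state fits
#'
#' Per-parameter arithmetic mean and sample standard deviation (n-1
#' denominator) across accepted replicate fits. The midpoint is
#' summarized from the per-replicate midpoints, not as mean dG over
#' mean m.
#'
#' @param fits List of `two_state_fit` objects; non-accepted fits are
#'   dropped with a warning.
#' @return An object of class `replicate_summary`: a `data.frame` with
#'   columns `parameter`, `mean`, `sd` plus attribute `n_replicates`.
#' @export
summarize_replicates <- function(fits) {
  stopifnot(all(vapply(fits, inherits, logical(1), "two_state_fit")))
  dropped <- !vapply(fits, `[[`, logical(1), "accepted")
  if (any(dropped)) {
    warning(sprintf("dropping %d non-accepted fit(s)", sum(dropped)))
    fits <- fits[!dropped]
  }
  if (length(fits) < 2L) {
    abort("replicate summary requires >= 2 accepted fits",
          "cyclofit_insufficient_replicates_error")
  }
  params <- c("yN0", "mN", "yU0", "mU", "dG_kJ_mol", "m_kJ_mol_M",
              "midpoint_M")
  vals <- sapply(params, function(p) vapply(fits, `[[`, numeric(1), p))
  out <- data.frame(
    parameter = params,
    mean = apply(vals, 2, mean),
    sd = apply(vals, 2, stats::sd),
    row.names = NULL
  )
  structure(out, n_replicates = length(fits),
            class = c("replicate_summary", "data.frame"))
}

#' Read an unfolding titration from delimited text
#'
#' Columns (urea_M, signal) or (refractive_index, signal) — the latter is
#' converted through [urea_from_refractive_index()] using the
#' `buffer_refractive_index` metadata key. Metadata `temperature_C` and
#' `replicate_id` populate the dataset fields.
#'
#' @param path Titration file.
#' @param blank_path Optional companion protein-free titration file.
#' @return An `unfolding_dataset`.
#' @export
read_titration <- function(path, blank_path = NULL) {
  raw <- read_xy_file(path)
  x <- raw$x
  if (identical(raw$meta$x_column, "refractive_index")) {
    nb <- raw$meta$buffer_refractive_index
    if (is.null(nb)) {
      abort("refractive-index file lacks buffer_refractive_index metadata",
            "cyclofit_io_error")
    }
    x <- urea_from_refractive_index(x, nb)
  }
  blank <- NULL
  if (!is.null(blank_path)) {
    braw <- read_xy_file(blank_path)
    blank <- data.frame(urea_M = braw$x, signal = braw$y)
  }
  tempC <- raw$meta$temperature_C %||% 15
  unfolding_dataset(x, raw$y, temperature_K = tempC + 273.15,
                    replicate_id = raw$meta$replicate_id %||% basename(path),
                    blank_series = blank)
}

#' @rdname read_titration
#' @param data An `unfolding_dataset` to serialize.
#' @export
write_titration <- function(data, path) {
  stopifnot(inherits(data, "unfolding_dataset"))
  write_xy_file(path, data$urea_M, data$signal,
                meta = list(temperature_C = data$temperature_K - 273.15,
                            replicate_id = data$replicate_id),
                columns = c("urea_M", "signal"))
}
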