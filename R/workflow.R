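# End-to-end pipelines: simulate or ingest -> fit -> summarize ->
# structured report, with the configuration and seed echoed into every
# output so any report can be regenerated bit-identically.

REPORT_SCHEMA_VERSION <- "1.0"

pkg_version <- function() {
  as.character(utils::packageVersion("cyclofit"))
}

#' Configuration for a pipeline run
#'
#' Exactly one of `input_paths` (delimited-text instrument files) or
#' `preset` (a synthetic-data truth object) must be supplied; the seed
#' is recorded in every output.
#'
#' @param input_paths Character vector of input files, or `NULL`.
#' @param preset An `unfolding_truth`/`assay_truth`, or `NULL`.
#' @param n_replicates Replicates to simulate (stability pipeline only).
#' @param seed Integer seed.
#' @param options Named list of stage options (fitting gates,
#'   model-selection gates, `dead_time_s`, `weighted`), passed through to
#'   the fitting functions.
#' @param verbose Emit per-fit progress messages.
#' @return A `run_config` object.
#' @export
run_config <- function(input_paths = NULL, preset = NULL,
                       n_replicates = 3L, seed = 1L, options = list(),
                       verbose = FALSE) {
  if (is.null(input_paths) == is.null(preset)) {
    abort("exactly one of `input_paths` or `preset` must be given",
          "cyclofit_config_error")
  }
  if (!is.null(input_paths) && length(input_paths) == 0L) {
    abort("`input_paths` is empty", "cyclofit_config_error")
  }
  structure(
    list(input_paths = input_paths, preset = preset,
         n_replicates = as.integer(n_replicates), seed = as.integer(seed),
         options = options, verbose = isTRUE(verbose)),
    class = "run_config"
  )
}

config_echo <- function(config) {
  list(
    mode = if (is.null(config$preset)) "files" else "simulation",
    input_paths = config$input_paths,
    preset_class = if (!is.null(config$preset)) class(config$preset)[1],
    preset = if (!is.null(config$preset)) unclass(config$preset),
    n_replicates = config$n_replicates,
    seed = config$seed,
    options = config$options
  )
}

log_msg <- function(verbose, ...) {
  if (verbose) message(sprintf(...))
}

#' Run the equilibrium-stability pipeline
#'
#' Ingest (or simulate) urea-unfolding titrations, blank-correct where a
#' blank series is present, fit each replicate with the two-state
#' linear-extrapolation model, and aggregate accepted fits into
#' replicate statistics. Individual replicate failures are recorded as
#' warnings in the report, not run aborts; a run with zero accepted fits
#' is an error.
#'
#' @param config A `run_config`. For simulation mode, `preset` must be
#'   an `unfolding_truth`; replicate datasets get seeds
#'   `child_seed(seed, i)`.
#' @return A `run_report` list: `schema_version`, `software_version`,
#'   `config`, `fits` (per-replicate parameter rows), `summary`
#'   (replicate means/SDs), `warnings`.
#' @export
run_stability_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$preset) &&
      !inherits(config$preset, "unfolding_truth")) {
    abort("stability pipeline needs an `unfolding_truth` preset",
          "cyclofit_config_error")
  }

  datasets <- if (is.null(config$preset)) {
    lapply(config$input_paths, read_titration)
  } else {
    lapply(seq_len(config$n_replicates), function(i) {
      generate_unfolding(config$preset, seed = child_seed(config$seed, i),
                         replicate_id = sprintf("sim%d", i))
    })
  }

  warnings <- list()
  fits <- list()
  for (ds in datasets) {
    log_msg(config$verbose, "fitting replicate %s", ds$replicate_id)
    res <- tryCatch(
      do.call(fit_two_state,
              c(list(ds), config$options[intersect(names(config$options),
                                                   c("restarts",
                                                     "jitter_seed",
                                                     "gates"))])),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      warnings[[length(warnings) + 1L]] <- list(
        replicate_id = ds$replicate_id, code = class(res)[1],
        message = conditionMessage(res))
    } else if (!res$accepted) {
      warnings[[length(warnings) + 1L]] <- list(
        replicate_id = ds$replicate_id, code = "fit_not_accepted",
        message = paste(res$reject_reason, collapse = ","))
      fits[[length(fits) + 1L]] <- res
    } else {
      fits[[length(fits) + 1L]] <- res
    }
  }

  accepted <- Filter(function(f) f$accepted, fits)
  if (length(accepted) == 0L) {
    abort("no replicate produced an accepted two-state fit",
          "cyclofit_run_error")
  }
  summary_tab <- if (length(accepted) >= 2L) {
    suppressWarnings(summarize_replicates(accepted))
  } else {
    NULL
  }

  fit_rows <- do.call(rbind, lapply(fits, function(f) {
    data.frame(replicate_id = f$replicate_id, yN0 = f$yN0, mN = f$mN,
               yU0 = f$yU0, mU = f$mU, dG_kJ_mol = f$dG_kJ_mol,
               m_kJ_mol_M = f$m_kJ_mol_M, midpoint_M = f$midpoint_M,
               residual_sd = f$residual_sd, accepted = f$accepted)
  }))

  structure(
    list(schema_version = REPORT_SCHEMA_VERSION,
         software_version = pkg_version(),
         pipeline = "stability",
         config = config_echo(config),
         fits = fit_rows,
         fit_objects = fits,
         summary = summary_tab,
         warnings = warnings),
    class = "run_report"
  )
}

#' Run the isomerase-activity pipeline
#'
#' Per-trace exponential fitting with automatic model selection,
#' identification of the PPIase-sensitive phase across the enzyme
#' concentration series, per-concentration replicate averaging, and the
#' specificity-constant regression per peptide x condition. Phase-
#' assignment ambiguities surface as per-peptide failures in
#' `warnings`, not run aborts.
#'
#' @param config A `run_config`. For simulation mode, `preset` must be
#'   an `assay_truth`.
#' @return A `run_report` with `specificity` (one row per peptide x
#'   condition: k0, kcat/KM, SDs, n), `rates` (per-concentration
#'   averages), `warnings`.
#' @export
run_activity_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$preset) && !inherits(config$preset, "assay_truth")) {
    abort("activity pipeline needs an `assay_truth` preset",
          "cyclofit_config_error")
  }

  traces <- if (is.null(config$preset)) {
    lapply(config$input_paths, read_trace)
  } else {
    generate_assay(config$preset, seed = config$seed)
  }

  opt <- config$options
  fit_args <- opt[intersect(names(opt),
                            c("dead_time_s", "restarts", "jitter_seed",
                              "min_rate_ratio",
                              "min_amplitude_fraction"))]

  keys <- vapply(traces, function(tr) {
    paste(tr$peptide_id, tr$condition, sep = "|")
  }, character(1))

  warnings <- list()
  spec_rows <- list()
  rate_rows <- list()

  for (key in unique(keys)) {
    group <- traces[keys == key]
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    pep <- parts[1]
    cond <- parts[2]
    log_msg(config$verbose, "analyzing %s (%s): %d traces", pep, cond,
            length(group))
    res <- tryCatch({
      fits <- lapply(group, function(tr) {
        do.call(select_model, c(list(tr), fit_args))$fit
      })
      fits <- identify_enzyme_sensitive_phase(fits)
      avg <- average_rates(fits)
      fit_specificity(avg, peptide_id = pep, condition = cond,
                      weighted = isTRUE(opt$weighted))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warnings[[length(warnings) + 1L]] <- list(
        peptide_id = pep, condition = cond, code = class(res)[1],
        message = conditionMessage(res))
      next
    }
    spec_rows[[length(spec_rows) + 1L]] <- data.frame(
      peptide_id = pep, condition = cond, k0_s = res$k0_s,
      k0_sd = res$k0_sd, kcat_over_KM_M_s = res$kcat_over_KM_M_s,
      kcat_over_KM_sd = res$kcat_over_KM_sd, n_points = res$n_points,
      accepted = res$accepted)
    rate_rows[[length(rate_rows) + 1L]] <-
      cbind(peptide_id = pep, condition = cond, res$points)
  }

  if (length(spec_rows) == 0L) {
    abort("no peptide produced a specificity estimate",
          "cyclofit_run_error")
  }

  structure(
    list(schema_version = REPORT_SCHEMA_VERSION,
         software_version = pkg_version(),
         pipeline = "activity",
         config = config_echo(config),
         specificity = do.call(rbind, spec_rows),
         rates = do.call(rbind, rate_rows),
         warnings = warnings),
    class = "run_report"
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report: %s pipeline, cyclofit %s, seed %d, %d warning(s)>\n",
              x$pipeline, x$software_version, x$config$seed,
              length(x$warnings)))
  if (!is.null(x$summary)) print(x$summary)
  if (!is.null(x$specificity)) print(x$specificity)
  invisible(x)
}

#' Write a run report to disk
#'
#' Serializes the report as versioned JSON plus flat tab-separated
#' summary tables next to it (`<stem>_fits.tsv` / `<stem>_summary.tsv`
#' for stability runs, `<stem>_specificity.tsv` / `<stem>_rates.tsv` for
#' activity runs).
#'
#' @param report A `run_report`.
#' @param path Output JSON path; tables share its stem.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  out <- report[setdiff(names(report), "fit_objects")]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  stem <- sub("\\.json$", "", path)
  write_tsv <- function(tab, suffix) {
    if (!is.null(tab)) {
      utils::write.table(tab, paste0(stem, "_", suffix, ".tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  if (identical(report$pipeline, "stability")) {
    write_tsv(report$fits, "fits")
    write_tsv(report$summary, "summary")
  } else {
    write_tsv(report$specificity, "specificity")
    write_tsv(report$rates, "rates")
  }
  invisible(path)
}
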