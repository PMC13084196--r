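#!/usr/bin/env Rscript
# Stage 2: equilibrium stability. Reads the replicate titration files
# written by 01_simulate.R, fits each with the two-state linear-
# extrapolation model, and reports per-protein midpoint, dG and m with
# replicate SDs. Expect midpoints near 4.6 M (CypA-like) and 3.6 M
# (CypB-like).

suppressMessages(library(cyclofit))

in_dir <- "results/simulated/titrations"
stopifnot(dir.exists(in_dir))
dir.create("results/stability", showWarnings = FALSE, recursive = TRUE)

for (prot in c("cypa", "cypb")) {
  paths <- list.files(in_dir, pattern = paste0("^", prot, "_"),
                      full.names = TRUE)
  report <- run_stability_pipeline(run_config(input_paths = paths))
  write_report(report, sprintf("results/stability/%s.json", prot))
  mid <- report$summary[report$summary$parameter == "midpoint_M", ]
  dg <- report$summary[report$summary$parameter == "dG_kJ_mol", ]
  cat(sprintf(
    "%s: midpoint %.2f +/- %.2f M urea, dG %.1f +/- %.1f kJ/mol (n = %d)\n",
    toupper(prot), mid$mean, mid$sd, dg$mean, dg$sd,
    attr(report$summary, "n_replicates")))
}
cat("reports under results/stability/\n")
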