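#!/usr/bin/env Rscript
# Stage 1: generate the synthetic instrument recordings that the later
# stages ingest, exactly as the analysis modules expect them on disk:
# three replicate urea titrations per protein (CypA-like and CypB-like
# stability regimes) and a full five-peptide isomerization assay under
# both buffer conditions. Ground truth goes into truth.json next to the
# data so recovery can be scored.

suppressMessages(library(cyclofit))

seed <- 20260930L
out_dir <- "results/simulated"
dir.create(file.path(out_dir, "titrations"), recursive = TRUE,
           showWarnings = FALSE)
dir.create(file.path(out_dir, "traces"), recursive = TRUE,
           showWarnings = FALSE)

truths <- list()

for (prot in c("cypa", "cypb")) {
  preset <- unfolding_preset(prot)
  truths[[paste0("unfolding_", prot)]] <- unclass(preset)
  for (i in 1:3) {
    ds <- generate_unfolding(preset, seed = seed + i * 17 +
                               ifelse(prot == "cypa", 0, 1000),
                             replicate_id = sprintf("%s_rep%d", prot, i))
    write_titration(ds, file.path(out_dir, "titrations",
                                  sprintf("%s_rep%d.tsv", prot, i)))
  }
}

for (cond in c("reducing", "er_mimicking")) {
  truth <- assay_preset("cypa", condition = cond)
  truths[[paste0("assay_cypa_", cond)]] <- unclass(truth)
  traces <- generate_assay(truth, seed = seed)
  for (j in seq_along(traces)) {
    tr <- traces[[j]]
    write_trace(tr, file.path(out_dir, "traces",
                              sprintf("cypa_%s_%s_%.0fnM_%s.tsv",
                                      cond, tr$peptide_id,
                                      tr$enzyme_concentration_M * 1e9,
                                      tr$replicate_id)))
  }
}

jsonlite::write_json(c(list(master_seed = seed), truths),
                     file.path(out_dir, "truth.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

n_tit <- length(list.files(file.path(out_dir, "titrations")))
n_tr <- length(list.files(file.path(out_dir, "traces")))
cat(sprintf("wrote %d titrations and %d kinetic traces under %s\n",
            n_tit, n_tr, out_dir))
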