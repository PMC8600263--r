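#!/usr/bin/env Rscript
# Stage 2: discovery from the files stage 1 wrote.
#
# Loads the four cohorts and the gene-set collection from TSV/GMT, runs the
# full discovery pipeline (PAS -> Cox ranking -> SIS -> crosstalk
# decomposition -> PAS on sub-pathways -> FDR filter -> cross-cohort panel
# -> 4:1 split -> K-means subtyping -> KNN classifier -> evaluation) and
# writes the panel, per-cohort feature statistics, subtype labels,
# diagnostics and the run manifest under results/discovery/.

suppressPackageStartupMessages(library(pascrosstalk))

indir <- "results/simulated"
outdir <- "results/discovery"
seed <- 20260927
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
if (!file.exists(file.path(indir, "gene_sets.gmt"))) {
  stop("run analysis/01_simulate.R first")
}

gene_sets <- read_gmt(file.path(indir, "gene_sets.gmt"))
cohort_names <- sprintf("cohort%02d", 1:4)
cohorts <- lapply(cohort_names, function(nm) {
  expr <- read_expression(file.path(indir, paste0(nm, "_expression.tsv")))
  surv <- read_survival(file.path(indir, paste0(nm, "_survival.tsv")))
  list(expr = expr, surv = surv)
})
names(cohorts) <- cohort_names

res <- run_discovery(cohorts, gene_sets, seed = seed)

# ---- persist every interesting artifact as plain text -----------------------
write_manifest(res$manifest, file.path(outdir, "manifest.json"))
writeLines(res$panel, file.path(outdir, "panel_features.txt"))
write_gmt(res$panel_collection, file.path(outdir, "panel_features.gmt"))
for (nm in cohort_names) {
  utils::write.table(res$per_cohort[[nm]]$stats,
                     file.path(outdir, paste0(nm, "_feature_stats.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}
utils::write.table(
  data.frame(sample_id = names(res$subtype_model$labels),
             subtype = unname(res$subtype_model$labels)),
  file.path(outdir, "training_subtypes.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(res$subtype_model$diagnostics,
                   file.path(outdir, "k_selection_diagnostics.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(res$cv$per_fold, file.path(outdir, "cv_folds.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
eval_tab <- do.call(rbind, lapply(names(res$reports), function(nm) {
  r <- res$reports[[nm]]
  data.frame(cohort = nm, c_index = r$c_index, brier = r$brier,
             logrank_p = r$logrank$p, auc = r$auc, t_star = r$t_star)
}))
utils::write.table(eval_tab, file.path(outdir, "evaluation_summary.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

# ---- narrative --------------------------------------------------------------
man <- res$manifest
cat(sprintf("screened %d pathways/cohort; crosstalk grew them to %d features (cohort01)\n",
            man$cohorts$cohort01$n_screened,
            man$cohorts$cohort01$n_crosstalk_features))
cat(sprintf("FDR < %.2g selections per cohort: %s\n",
            man$params$fdr_alpha,
            paste(vapply(man$cohorts, function(x) x$n_fdr_selected, numeric(1)),
                  collapse = ", ")))
cat(sprintf("cross-cohort panel: %d features (intersected over cohorts %s)\n",
            man$panel_size, paste(man$params$intersect_idx, collapse = ", ")))
cat(sprintf("selected k = %d; training split %d/%d; CV accuracy %.3f, AUC %.3f\n",
            man$selected_k, man$split$n_train, man$split$n_test,
            man$cv$mean_accuracy, man$cv$mean_auc))
cat("per-cohort evaluation written to evaluation_summary.tsv:\n")
print(eval_tab, row.names = FALSE, digits = 3)
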