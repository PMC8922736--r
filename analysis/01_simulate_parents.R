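#!/usr/bin/env Rscript
# Simulate the parent datasets the downstream analyses reuse:
#   - a "signal" parent: 5000 genes, 100 + 100 samples, 5% true DEGs,
#     2% outlier entries (the semi-synthetic benchmark's source data);
#   - a "contaminated null" parent: 2000 genes, 50 + 50 samples, no true
#     DEGs, 5% outlier entries (the permutation-null experiment's data).
# Full count matrices go under scratch/parents/ (bulky raw data); the small
# labels, truth lists and per-sample summaries go under results/parents/.

suppressMessages(library(degbench))

seed <- 1L
outdir <- "results/parents"
rawdir <- "scratch/parents"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
dir.create(rawdir, recursive = TRUE, showWarnings = FALSE)

signal <- simulate_dataset(sim_config(G = 5000L, n1 = 100L, n2 = 100L,
                                      pi = 0.05, epsilon = 0.02,
                                      seed = derive_seed(seed, 42L)))
null_c <- simulate_dataset(sim_config(G = 2000L, n1 = 50L, n2 = 50L,
                                      pi = 0, epsilon = 0.05,
                                      seed = derive_seed(seed, 8L)))

save_parent <- function(ds, tag) {
  write_count_matrix(ds$counts, file.path(rawdir, paste0(tag, "_counts.tsv")),
                     meta = list(seed = ds$config$seed, G = ds$config$G,
                                 pi = ds$config$pi, epsilon = ds$config$epsilon))
  write_labels(ds$labels, file.path(outdir, paste0(tag, "_labels.tsv")))
  writeLines(ds$truth$true_deg_ids, file.path(outdir, paste0(tag, "_truth.txt")))
  write_tsv_meta(data.frame(sample_id = colnames(ds$counts),
                            condition = as.character(ds$labels),
                            library_size = colSums(ds$counts),
                            outlier_entries = colSums(ds$outlier_mask)),
                 file.path(outdir, paste0(tag, "_sample_summary.tsv")),
                 meta = list(seed = ds$config$seed, G = ds$config$G,
                             pi = ds$config$pi, epsilon = ds$config$epsilon))
  message(sprintf("%s: %d genes x %d samples, %d true DEGs, %d outlier entries (%.2f%%)",
                  tag, nrow(ds$counts), ncol(ds$counts),
                  length(ds$truth$true_deg_ids), sum(ds$outlier_mask),
                  100 * mean(ds$outlier_mask)))
}

save_parent(signal, "signal")
save_parent(null_c, "contaminated_null")
message("library size summary (signal parent):")
print(summary(colSums(signal$counts)))
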