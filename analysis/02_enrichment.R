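#!/usr/bin/env Rscript
# Pull-down enrichment-ratio hit calling per cell line and the
# cross-cell-line hit overlap. For each gene the enrichment ratio
# (PD_test/PD_control)/(input_test/input_control) is averaged over
# replicates and probes; a log-normal background is fitted on log2 ratios
# and genes >= 1 SD above its mean are hits.

suppressPackageStartupMessages(library(mirpulldown))

data_dir <- "results/data"
out_dir <- "results/enrichment"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

hit_sets <- list()
for (cl in c("CL1", "CL2")) {
  d <- file.path(data_dir, cl)
  pm <- read_matrix(file.path(d, "matrix.tsv"), file.path(d, "design.tsv"),
                    file.path(d, "probe_map.tsv"))
  flags <- flag_expressed(pm)        # background = 5th intensity percentile
  tab <- enrichment_ratio(pm, flags, cell_line = cl)
  thr <- fit_background(tab, n_sd = 1)
  hits <- call_hits(tab, thr, label = paste0("hits_", cl))
  message(sprintf("%s: %d expressed genes; 1 SD threshold = %.2f-fold; %d hits",
                  cl, nrow(tab), thr$fold_equivalent, length(hits)))
  write_enrichment_table(tab, thr, file.path(out_dir, paste0("enrichment_", cl, ".tsv")))
  write_gene_list(hits, file.path(out_dir, paste0("hits_", cl, ".txt")))
  writeLines(tab$gene_id, file.path(out_dir, paste0("expressed_", cl, ".txt")))
  hit_sets[[cl]] <- hits
}

both <- overlap(hit_sets$CL1, hit_sets$CL2)
both$label <- "overlap"
rep <- overlap_report(hit_sets$CL1, hit_sets$CL2)
write.table(rep, file.path(out_dir, "overlap_report.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_gene_list(both, file.path(out_dir, "overlap_hits.txt"))
message(sprintf("overlap: %d genes hit in both cell lines (%d only CL1, %d only CL2)",
                rep$both, rep$a_only, rep$b_only))

truth <- read.delim(file.path(data_dir, "truth.tsv"))
message(sprintf("of the overlap, %.0f%% are planted targets",
                100 * mean(both$members %in% truth$gene_id[truth$is_target])))
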