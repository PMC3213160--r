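#!/usr/bin/env Rscript
# Down-regulation calling from the input arms (fold change test/control
# transfection; genes reduced by >= 20% are down-regulated) and CDF/KS
# comparison of fold-change distributions: hits, down-regulated and overlap
# sets against all expressed genes, plus nested enrichment-ratio strata.

suppressPackageStartupMessages(library(mirpulldown))

data_dir <- "results/data"
enr_dir <- "results/enrichment"
out_dir <- "results/downregulation"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

all_cmp <- list()
for (cl in c("CL1", "CL2")) {
  d <- file.path(data_dir, cl)
  pm <- read_matrix(file.path(d, "matrix.tsv"), file.path(d, "design.tsv"),
                    file.path(d, "probe_map.tsv"))
  flags <- flag_expressed(pm)
  fc <- fold_change(pm, flags, cell_line = cl)
  down <- call_down(fc, cutoff = 0.8, label = paste0("down_", cl))
  message(sprintf("%s: %d of %d genes down-regulated by >= 20%%",
                  cl, length(down), nrow(fc)))
  write_fold_change_table(fc, 0.8, file.path(out_dir, paste0("fold_change_", cl, ".tsv")))
  write_gene_list(down, file.path(out_dir, paste0("down_", cl, ".txt")))

  hits <- read_gene_list(file.path(enr_dir, paste0("hits_", cl, ".txt")),
                         label = paste0("hits_", cl))
  ovl <- read_gene_list(file.path(enr_dir, "overlap_hits.txt"), label = "overlap")
  expressed <- gene_set(fc$gene_id, label = paste0("expressed_", cl))
  message(sprintf("%s: %.0f%% of down-regulated genes were also pulled down",
                  cl, 100 * mean(down$members %in% hits$members)))

  # nested enrichment strata: higher pull-down enrichment, stronger knockdown
  enr <- read.delim(file.path(enr_dir, paste0("enrichment_", cl, ".tsv")))
  strata <- stratify_by_enrichment(enr, c(1, 2, 4))
  cmp <- cdf_compare(fc, c(list(hits, down, ovl), strata), expressed)
  all_cmp[[cl]] <- cmp
  write.table(cdf_table(fc, c(list(hits, down, ovl, expressed), strata)),
              file.path(out_dir, paste0("cdf_", cl, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (i in seq_len(nrow(cmp)))
    message(sprintf("  KS %s vs %s: D = %.3f, p = %.3g",
                    cmp$set_a[i], cmp$set_b[i], cmp$ks_D[i], cmp$ks_p[i]))
}
cmp <- do.call(rbind, all_cmp)
write.table(cmp, file.path(out_dir, "ks_comparisons.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
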