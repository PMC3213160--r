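#!/usr/bin/env Rscript
# Hypergeometric pathway over-representation for the hit, down and overlap
# gene sets over the expressed-gene universe, and export of the
# pathway-overlap network (nodes = pathways with p < 0.001, edges = shared
# query genes) as SIF + node attributes.

suppressPackageStartupMessages(library(mirpulldown))

data_dir <- "results/data"
enr_dir <- "results/enrichment"
dn_dir <- "results/downregulation"
out_dir <- "results/pathways"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

universe <- union(readLines(file.path(enr_dir, "expressed_CL1.txt")),
                  readLines(file.path(enr_dir, "expressed_CL2.txt")))
pathways <- read_gmt(file.path(data_dir, "pathways.gmt"), universe = universe)
message(sprintf("universe of %d expressed genes; %d pathways after intersection",
                length(pathways$universe), length(pathways$pathways)))

sets <- list()
for (cl in c("CL1", "CL2")) {
  sets[[paste0("hits_", cl)]] <-
    read_gene_list(file.path(enr_dir, paste0("hits_", cl, ".txt")), paste0("hits_", cl))
  sets[[paste0("down_", cl)]] <-
    read_gene_list(file.path(dn_dir, paste0("down_", cl, ".txt")), paste0("down_", cl))
}
sets$overlap <- read_gene_list(file.path(enr_dir, "overlap_hits.txt"), "overlap")

for (lbl in names(sets)) {
  res <- suppressWarnings(enrich_pathways(sets[[lbl]], pathways, p_cut = 0.001))
  write.table(res, file.path(out_dir, paste0("pathways_", lbl, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  net <- build_network(res, sets[[lbl]], pathways, p_cut = 0.001)
  write_network(net, file.path(out_dir, paste0("network_", lbl, ".sif")),
                file.path(out_dir, paste0("network_", lbl, "_nodes.tsv")))
  message(sprintf("%s: %d/%d pathways significant at p < 0.001; network %d nodes, %d edges; top: %s (p = %.2g)",
                  lbl, sum(res$significant), nrow(res), nrow(net$nodes),
                  nrow(net$edges), res$pathway_id[1], res$p[1]))
}
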