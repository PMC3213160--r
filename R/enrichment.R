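#' @noRd
arm_sample <- function(design, arm, mirna, replicate) {
  id <- design$sample_id[design$arm == arm & design$mirna == mirna &
                           design$replicate == replicate]
  if (length(id) != 1L)
    stopf("design does not resolve a unique sample for (%s, %s, replicate %d)",
          arm, mirna, replicate)
  id
}

#' Per-probe, per-replicate ratio matrix for a single cell line
#'
#' `kind = "enrichment"` computes the pull-down enrichment ratio
#' (PD_test/PD_control)/(input_test/input_control); `kind = "fold_change"`
#' computes the input-arm fold change input_test/input_control.
#' @noRd
probe_replicate_ratios <- function(x, kind = c("enrichment", "fold_change")) {
  kind <- match.arg(kind)
  d <- x$design
  reps <- sort(unique(d$replicate))
  v <- x$values
  out <- matrix(NA_real_, nrow(v), length(reps),
                dimnames = list(rownames(v), paste0("rep", reps)))
  for (j in seq_along(reps)) {
    r <- reps[j]
    in_t <- v[, arm_sample(d, "input", "test", r)]
    in_c <- v[, arm_sample(d, "input", "control", r)]
    if (kind == "enrichment") {
      pd_t <- v[, arm_sample(d, "pulldown", "test", r)]
      pd_c <- v[, arm_sample(d, "pulldown", "control", r)]
      num <- pd_t / pd_c
      den <- in_t / in_c
      bad <- pd_t <= 0 | pd_c <= 0 | in_t <= 0 | in_c <= 0
      out[, j] <- ifelse(bad, NA_real_, num / den)
    } else {
      bad <- in_t <= 0 | in_c <= 0
      out[, j] <- ifelse(bad, NA_real_, in_t / in_c)
    }
  }
  out
}

#' @noRd
ratio_table <- function(x, flags, cell_line, average, kind) {
  stopifnot(inherits(x, "ProbeMatrix"))
  x1 <- subset_cell_line(x, cell_line)
  cl <- unique(x1$design$cell_line)
  rat <- probe_replicate_ratios(x1, kind)

  # a nonpositive intensity anywhere in a gene's terms makes its ratio
  # undefined: the whole gene is excluded and counted
  probe_bad <- apply(is.na(rat), 1L, any)
  map <- x1$probe_map
  bad_genes <- unique(map$gene_id[map$probe_id %in% rownames(rat)[probe_bad]])

  per_probe <- if (average == "arithmetic") rowMeans(rat) else 2^rowMeans(log2(rat))

  keep_genes <- NULL
  if (!is.null(flags)) {
    stopifnot(inherits(flags, "ExpressionFlag"))
    keep_genes <- names(flags$gene)[flags$gene]
  }
  gene_ratio <- collapse_to_genes(per_probe, map, average = average)
  gene_ratio <- gene_ratio[!(names(gene_ratio) %in% bad_genes)]
  if (!is.null(keep_genes)) gene_ratio <- gene_ratio[names(gene_ratio) %in% keep_genes]
  if (length(bad_genes))
    message(sprintf("%s: excluded %d gene(s) with nonpositive intensities", cl,
                    length(bad_genes)))

  np <- probes_per_gene_count(rownames(rat), map)
  tab <- data.frame(gene_id = names(gene_ratio),
                    mean_ratio = as.numeric(gene_ratio),
                    log2_ratio = log2(as.numeric(gene_ratio)),
                    n_probes = as.integer(np[names(gene_ratio)]),
                    n_replicates_used = ncol(rat),
                    cell_line = cl,
                    row.names = NULL)
  attr(tab, "n_excluded_nonpositive") <- length(bad_genes)
  attr(tab, "average") <- average
  tab
}

#' Per-gene pull-down enrichment ratio
#'
#' For each probe and biological replicate the enrichment ratio
#' \deqn{\frac{PD_{test}/PD_{control}}{input_{test}/input_{control}}}
#' is computed, replicate ratios are averaged (arithmetic mean by default),
#' and probes are collapsed to genes with [collapse_to_genes()]. Normalizing
#' the pull-down to the input cancels abundance-driven nonspecific bead
#' capture and folds target knockdown into the denominator. Unexpressed genes
#' (per `flags`) are excluded; genes with any zero or negative intensity among
#' their ratio terms are excluded with a logged count.
#'
#' @param x a [probe_matrix()] containing all four arms for `cell_line`.
#' @param flags optional [flag_expressed()] result; `NULL` keeps all genes.
#' @param cell_line cell line to analyse; may be omitted when the matrix holds
#'   exactly one.
#' @param average `"arithmetic"` (default) or `"geometric"`, applied both to
#'   the replicate mean and the probe collapse.
#' @return an `EnrichmentTable` data.frame: `gene_id`, `mean_ratio`,
#'   `log2_ratio`, `n_probes`, `n_replicates_used`, `cell_line`.
#' @export
enrichment_ratio <- function(x, flags = NULL, cell_line = NULL,
                             average = c("arithmetic", "geometric")) {
  average <- match.arg(average)
  tab <- ratio_table(x, flags, cell_line, average, "enrichment")
  class(tab) <- c("EnrichmentTable", "data.frame")
  tab
}

#' Fit the log-normal background of enrichment ratios
#'
#' The background model is a log-normal distribution over the full set of
#' expressed genes: `mu` and `sigma` are the sample mean and sample SD
#' (n-1 denominator) of the log2 mean ratios. The hit threshold in fold units
#' is `2^(mu + n_sd * sigma)`.
#'
#' @param table an `EnrichmentTable` from [enrichment_ratio()].
#' @param n_sd SD multiplier for the hit threshold (default 1).
#' @return object of class `HitThreshold`: list `mu`, `sigma`, `n_sd`,
#'   `fold_equivalent`.
#' @export
fit_background <- function(table, n_sd = 1) {
  check_scalar(n_sd, "n_sd", lower = 0)
  l <- table$log2_ratio[is.finite(table$log2_ratio)]
  if (length(l) < 2L)
    stopf("need at least 2 genes with finite ratios to fit the background (got %d)",
          length(l))
  mu <- mean(l); sigma <- sd(l)
  structure(list(mu = mu, sigma = sigma, n_sd = n_sd,
                 fold_equivalent = 2^(mu + n_sd * sigma)),
            class = "HitThreshold")
}

#' @export
print.HitThreshold <- function(x, ...) {
  cat(sprintf("HitThreshold: log2 mu = %.4f, sigma = %.4f; %g SD above background = %.3f-fold\n",
              x$mu, x$sigma, x$n_sd, x$fold_equivalent))
  invisible(x)
}

#' Call pull-down hits at an SD-based threshold
#'
#' Genes whose mean enrichment ratio is greater than or equal to the
#' threshold's fold equivalent (boundary inclusive) are hits. The universe of
#' the returned set is all genes in the table.
#'
#' @param table an `EnrichmentTable`.
#' @param threshold a [fit_background()] result (fitted on the same table).
#' @param label label for the returned set.
#' @return a [gene_set()] of hits.
#' @export
call_hits <- function(table, threshold, label = "hits") {
  stopifnot(inherits(threshold, "HitThreshold"))
  gene_set(table$gene_id[table$mean_ratio >= threshold$fold_equivalent],
           label = label, universe = table$gene_id)
}

#' Stratify genes by increasing enrichment-ratio cutoffs
#'
#' Returns nested gene sets: genes with mean ratio at or above each cutoff.
#' Raising the cutoff can only shrink the set.
#'
#' @param table an `EnrichmentTable`.
#' @param cutoffs numeric vector of fold cutoffs, sorted ascending.
#' @return list of [gene_set()]s, one per cutoff.
#' @export
stratify_by_enrichment <- function(table, cutoffs) {
  if (is.unsorted(cutoffs)) stopf("'cutoffs' must be sorted ascending")
  lapply(cutoffs, function(cut) {
    gene_set(table$gene_id[table$mean_ratio >= cut],
             label = sprintf("ratio>=%g", cut), universe = table$gene_id)
  })
}

#' Write an enrichment table as TSV, annotated with hit calls
#'
#' @param table an `EnrichmentTable`.
#' @param threshold a [fit_background()] result.
#' @param path output TSV path.
#' @export
write_enrichment_table <- function(table, threshold, path) {
  out <- as.data.frame(table)
  out$is_hit <- out$mean_ratio >= threshold$fold_equivalent
  out$threshold_fold <- threshold$fold_equivalent
  write_tsv(out[, c("gene_id", "mean_ratio", "log2_ratio", "n_probes",
                    "n_replicates_used", "is_hit", "threshold_fold", "cell_line")],
            path)
}
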