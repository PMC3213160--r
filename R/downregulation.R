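#' Per-gene input-arm fold change after test-miRNA transfection
#'
#' For each probe and replicate the fold change input_test/input_control is
#' computed, averaged over replicates, and collapsed to genes — the same order
#' of operations as [enrichment_ratio()]. A fold change below 1 means the
#' transcript fell after over-expressing the test miRNA.
#'
#' @inheritParams enrichment_ratio
#' @return a `FoldChangeTable` data.frame: `gene_id`, `mean_fc`, `log2_fc`,
#'   `n_probes`, `n_replicates_used`, `cell_line`.
#' @export
fold_change <- function(x, flags = NULL, cell_line = NULL,
                        average = c("arithmetic", "geometric")) {
  average <- match.arg(average)
  tab <- ratio_table(x, flags, cell_line, average, "fold_change")
  names(tab)[names(tab) == "mean_ratio"] <- "mean_fc"
  names(tab)[names(tab) == "log2_ratio"] <- "log2_fc"
  class(tab) <- c("FoldChangeTable", "data.frame")
  tab
}

#' Call down-regulated genes
#'
#' A gene is down-regulated when its mean input-arm ratio decreased by at
#' least `1 - cutoff` (default cutoff 0.8, i.e. at least a 20% reduction,
#' boundary inclusive).
#'
#' @param table a `FoldChangeTable` from [fold_change()].
#' @param cutoff fold-change cutoff in (0, 1); genes with `mean_fc <= cutoff`
#'   are called down.
#' @param label label for the returned set.
#' @return a [gene_set()] of down-regulated genes with the table's genes as
#'   universe.
#' @export
call_down <- function(table, cutoff = 0.8, label = "down") {
  check_scalar(cutoff, "down_cutoff", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  gene_set(table$gene_id[table$mean_fc <= cutoff],
           label = label, universe = table$gene_id)
}

#' Two-sample KS comparison of log2 fold changes between gene sets
#'
#' Each set is intersected with the genes that have fold changes, then its
#' log2 fold-change distribution is compared to the reference set with the
#' two-sample Kolmogorov-Smirnov statistic D = sup|F_a - F_b| and the
#' asymptotic p-value. Sets with fewer than 2 usable genes are skipped with a
#' warning. The statistic is invariant under any strictly monotone transform
#' of the fold changes, so log2 vs linear scale makes no difference to D.
#'
#' @param table a `FoldChangeTable`.
#' @param sets list of [gene_set()]s to compare against the reference.
#' @param reference [gene_set()] used as the comparison baseline (e.g. all
#'   expressed genes).
#' @return a `KSComparison` data.frame: `set_a`, `set_b`, `n_a`, `n_b`,
#'   `ks_D`, `ks_p`.
#' @export
cdf_compare <- function(table, sets, reference) {
  stopifnot(inherits(reference, "GeneSet"))
  if (inherits(sets, "GeneSet")) sets <- list(sets)
  fc <- setNames(table$log2_fc, table$gene_id)
  ref <- fc[names(fc) %in% reference$members]
  if (length(ref) < 2L)
    stopf("reference set '%s' has fewer than 2 genes with fold changes", reference$label)
  rows <- lapply(sets, function(s) {
    a <- fc[names(fc) %in% s$members]
    if (length(a) < 2L) {
      warnf("set '%s' has fewer than 2 genes with fold changes; comparison skipped",
            s$label)
      return(NULL)
    }
    ks <- ks_two_sample(a, ref)
    data.frame(set_a = s$label, set_b = reference$label,
               n_a = length(a), n_b = length(ref),
               ks_D = ks$statistic, ks_p = ks$p_value)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(set_a = character(0), set_b = character(0),
                      n_a = integer(0), n_b = integer(0),
                      ks_D = numeric(0), ks_p = numeric(0))
  class(out) <- c("KSComparison", "data.frame")
  out
}

#' Two-sample KS statistic and asymptotic p
#'
#' D is evaluated at all pooled data points (ties handled by taking the sup
#' over distinct values); p comes from the asymptotic Kolmogorov distribution
#' with the standard effective sample size. Exact small-sample p-values are
#' not used.
#' @noRd
ks_two_sample <- function(a, b) {
  kt <- suppressWarnings(ks.test(a, b, exact = FALSE))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Empirical CDF table of log2 fold changes for plotting
#'
#' @param table a `FoldChangeTable`.
#' @param sets list of [gene_set()]s (or a single one).
#' @return long data.frame: `set`, `log2_fc` (sorted), `cum_fraction`.
#' @export
cdf_table <- function(table, sets) {
  if (inherits(sets, "GeneSet")) sets <- list(sets)
  fc <- setNames(table$log2_fc, table$gene_id)
  do.call(rbind, lapply(sets, function(s) {
    v <- sort(fc[names(fc) %in% s$members])
    if (!length(v)) return(NULL)
    data.frame(set = s$label, log2_fc = as.numeric(v),
               cum_fraction = seq_along(v) / length(v), row.names = NULL)
  }))
}

#' Write fold-change results as TSV, annotated with down calls
#'
#' @param table a `FoldChangeTable`.
#' @param cutoff fold-change cutoff used for the `is_down` flag.
#' @param path output TSV path.
#' @export
write_fold_change_table <- function(table, cutoff = 0.8, path) {
  out <- as.data.frame(table)
  out$is_down <- out$mean_fc <= cutoff
  out$cutoff <- cutoff
  write_tsv(out[, c("gene_id", "mean_fc", "log2_fc", "n_probes",
                    "n_replicates_used", "is_down", "cutoff", "cell_line")], path)
}
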