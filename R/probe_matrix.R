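#' Construct a probe-level expression matrix with its sample design
#'
#' Bundles normalized probe intensities with the four-arm sample design
#' (pull-down and input arms, each under test- and control-miRNA transfection,
#' with replicates) and the probe-to-gene map. Validation enforces the design
#' grid: within each cell line every (arm, mirna, replicate) combination must
#' be present exactly once.
#'
#' @param values numeric matrix, probes x samples; rownames are probe ids,
#'   colnames are sample ids matching `design$sample_id`. Intensities are
#'   normalized (e.g. RMA) linear-scale values and must be non-negative.
#' @param design data.frame with columns `sample_id`, `arm` (`pulldown` or
#'   `input`), `mirna` (`test` or `control`), `replicate` (integer index) and
#'   `cell_line`.
#' @param probe_map data.frame with columns `probe_id`, `gene_id`. Probes
#'   absent from the map are retained in the matrix but flagged unmapped and
#'   excluded from gene-level results.
#' @return an object of class `ProbeMatrix`: a list with elements `values`,
#'   `design`, `probe_map`.
#' @export
probe_matrix <- function(values, design, probe_map) {
  if (!is.matrix(values) || !is.numeric(values))
    stopf("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("'values' must have probe ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stopf("duplicate probe_id in matrix: %s",
          rownames(values)[duplicated(rownames(values))][1L])
  if (any(!is.finite(values)))
    stopf("non-numeric or missing cell in matrix (first at probe '%s')",
          rownames(values)[which(!is.finite(values), arr.ind = TRUE)[1L, 1L]])
  if (any(values < 0)) stopf("negative intensity in matrix; input must be normalized non-negative values")

  design <- validate_design(design)
  miss <- setdiff(design$sample_id, colnames(values))
  if (length(miss))
    stopf("matrix is missing sample column(s): %s", paste(miss, collapse = ", "))
  values <- values[, design$sample_id, drop = FALSE]

  stopifnot(is.data.frame(probe_map))
  if (!all(c("probe_id", "gene_id") %in% names(probe_map)))
    stopf("probe map must have columns 'probe_id' and 'gene_id'")
  probe_map <- unique(probe_map[, c("probe_id", "gene_id")])
  dup <- probe_map$probe_id[duplicated(probe_map$probe_id)]
  if (length(dup))
    stopf("probe '%s' is mapped to more than one gene", dup[1L])

  structure(list(values = values, design = design, probe_map = probe_map),
            class = "ProbeMatrix")
}

#' @noRd
validate_design <- function(design) {
  req <- c("sample_id", "arm", "mirna", "replicate", "cell_line")
  if (!is.data.frame(design) || !all(req %in% names(design)))
    stopf("design must be a data.frame with columns %s", paste(req, collapse = ", "))
  design$arm <- as.character(design$arm)
  design$mirna <- as.character(design$mirna)
  design$cell_line <- as.character(design$cell_line)
  design$replicate <- as.integer(design$replicate)
  if (!all(design$arm %in% c("pulldown", "input")))
    stopf("design 'arm' must be 'pulldown' or 'input'")
  if (!all(design$mirna %in% c("test", "control")))
    stopf("design 'mirna' must be 'test' or 'control'")
  if (anyDuplicated(design$sample_id))
    stopf("duplicate sample_id in design")
  for (cl in unique(design$cell_line)) {
    d <- design[design$cell_line == cl, ]
    reps <- sort(unique(d$replicate))
    if (length(reps) < 1L) stopf("cell line '%s' has no replicates", cl)
    grid <- expand.grid(arm = c("pulldown", "input"), mirna = c("test", "control"),
                        replicate = reps, stringsAsFactors = FALSE)
    key_have <- paste(d$arm, d$mirna, d$replicate)
    key_want <- paste(grid$arm, grid$mirna, grid$replicate)
    miss <- setdiff(key_want, key_have)
    if (length(miss))
      stopf("design for cell line '%s' is missing combination (arm mirna replicate): %s",
            cl, miss[1L])
    if (anyDuplicated(key_have))
      stopf("design for cell line '%s' has a duplicated (arm, mirna, replicate) combination", cl)
  }
  design
}

#' Read a probe matrix, its sample design and probe-to-gene map from TSV files
#'
#' The matrix file has a `probe_id` column followed by one column per sample;
#' the design file has columns `sample_id`, `arm`, `mirna`, `replicate`,
#' `cell_line`; the map file has `probe_id`, `gene_id`. Readers tolerate CRLF
#' and `#` comment lines.
#'
#' @param matrix_file,design_file,map_file paths to the three TSV files.
#' @return a validated [probe_matrix()].
#' @export
read_matrix <- function(matrix_file, design_file, map_file) {
  tab <- read_tsv(matrix_file)
  if (names(tab)[1L] != "probe_id")
    stopf("%s: first column must be 'probe_id' (found '%s')", matrix_file, names(tab)[1L])
  if (anyDuplicated(tab$probe_id))
    stopf("%s: duplicate probe_id '%s' (row %d)", matrix_file,
          tab$probe_id[duplicated(tab$probe_id)][1L],
          which(duplicated(tab$probe_id))[1L])
  for (j in seq_along(tab)[-1L]) {
    if (is.numeric(tab[[j]])) next
    num <- suppressWarnings(as.numeric(tab[[j]]))
    bad <- which(is.na(num))[1L]
    if (!is.na(bad))
      stopf("%s: non-numeric cell at row %d (probe '%s'), column '%s'",
            matrix_file, bad, tab$probe_id[bad], names(tab)[j])
    tab[[j]] <- num
  }
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  bad <- which(!is.finite(vals), arr.ind = TRUE)
  if (nrow(bad))
    stopf("%s: missing value at row %d (probe '%s'), column '%s'", matrix_file,
          bad[1L, 1L], tab$probe_id[bad[1L, 1L]], colnames(vals)[bad[1L, 2L]])
  rownames(vals) <- tab$probe_id
  storage.mode(vals) <- "double"
  design <- read_tsv(design_file)
  map <- read_tsv(map_file)
  probe_matrix(vals, design, map)
}

#' @export
print.ProbeMatrix <- function(x, ...) {
  cat(sprintf("ProbeMatrix: %d probes x %d samples; %d cell line(s); %d mapped probes\n",
              nrow(x$values), ncol(x$values), length(unique(x$design$cell_line)),
              sum(rownames(x$values) %in% x$probe_map$probe_id)))
  invisible(x)
}

#' Subset a ProbeMatrix to one cell line
#' @noRd
subset_cell_line <- function(x, cell_line) {
  if (is.null(cell_line)) {
    cls <- unique(x$design$cell_line)
    if (length(cls) > 1L)
      stopf("matrix holds %d cell lines; pass 'cell_line' explicitly", length(cls))
    cell_line <- cls
  }
  keep <- x$design$cell_line == cell_line
  if (!any(keep)) stopf("cell line '%s' not present in design", cell_line)
  structure(list(values = x$values[, x$design$sample_id[keep], drop = FALSE],
                 design = x$design[keep, , drop = FALSE],
                 probe_map = x$probe_map),
            class = "ProbeMatrix")
}

#' Flag expressed probes and genes
#'
#' A probe is called expressed when its signal exceeds the background level in
#' at least one sample; a gene is expressed when at least one of its probes
#' is. Downstream stages drop unexpressed genes. Arrays' native present/absent
#' calls are not available to this pipeline, so background is a reproducible
#' surrogate: either an absolute intensity or (default) a quantile of the
#' whole matrix.
#'
#' @param x a [probe_matrix()].
#' @param background absolute intensity threshold; if `NULL` (default), the
#'   `bg_quantile` quantile of all intensities is used.
#' @param bg_quantile quantile of the pooled intensity distribution used when
#'   `background` is `NULL` (default 0.05).
#' @return an object of class `ExpressionFlag`: list with logical vectors
#'   `probe` (named by probe id), `gene` (named by gene id) and the numeric
#'   `background` used.
#' @export
flag_expressed <- function(x, background = NULL, bg_quantile = 0.05) {
  stopifnot(inherits(x, "ProbeMatrix"))
  if (is.null(background))
    background <- as.numeric(quantile(x$values, bg_quantile, names = FALSE))
  check_scalar(background, "background", lower = 0)
  probe <- apply(x$values > background, 1L, any)
  map <- x$probe_map[x$probe_map$probe_id %in% names(probe), ]
  gene <- tapply(probe[map$probe_id], map$gene_id, any)
  gene <- setNames(as.logical(gene), names(gene))
  structure(list(probe = probe, gene = gene, background = background),
            class = "ExpressionFlag")
}

#' Collapse per-probe ratios to genes
#'
#' For genes represented by multiple probes the mean ratio over all probes is
#' taken; single-probe genes pass through unchanged. The arithmetic mean on
#' the linear ratio scale is the default; a geometric mean is available.
#'
#' @param per_probe_ratios named numeric vector of finite positive ratios,
#'   names are probe ids.
#' @param probe_map data.frame `probe_id`, `gene_id`; probes without a mapping
#'   are dropped.
#' @param average `"arithmetic"` (default) or `"geometric"`.
#' @return named numeric vector of per-gene ratios.
#' @export
collapse_to_genes <- function(per_probe_ratios, probe_map,
                              average = c("arithmetic", "geometric")) {
  average <- match.arg(average)
  stopifnot(is.numeric(per_probe_ratios), !is.null(names(per_probe_ratios)))
  keep <- is.finite(per_probe_ratios) & per_probe_ratios > 0
  r <- per_probe_ratios[keep]
  map <- probe_map[match(names(r), probe_map$probe_id), ]
  ok <- !is.na(map$gene_id)
  r <- r[ok]; g <- map$gene_id[ok]
  if (!length(r)) return(setNames(numeric(0), character(0)))
  out <- if (average == "arithmetic") {
    tapply(r, g, mean)
  } else {
    exp(tapply(log(r), g, mean))
  }
  setNames(as.numeric(out), names(out))
}

#' Number of probes per gene among a set of probes
#' @noRd
probes_per_gene_count <- function(probe_ids, probe_map) {
  map <- probe_map[probe_map$probe_id %in% probe_ids, ]
  tab <- table(map$gene_id)
  setNames(as.integer(tab), names(tab))
}
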