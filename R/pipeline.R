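#' Validate a pipeline configuration file
#'
#' The config is a single YAML file naming the per-cell-line inputs and the
#' analysis thresholds. Schema:
#'
#' ```yaml
#' cell_lines:
#'   - name: HCT116
#'     matrix: path/to/matrix.tsv
#'     design: path/to/design.tsv
#'     probe_map: path/to/probe_map.tsv
#' fasta: path/to/sequences.fasta
#' gmt: path/to/pathways.gmt
#' mirna: UGGCAGUGUCUUAGCUGGUUGU
#' thresholds: {n_sd: 1, down_cutoff: 0.8, pathway_p: 0.001}
#' expression_background: {quantile: 0.05}   # or {absolute: <intensity>}
#' hexamer: {n_sims: 1000, rng_seed: 1, regions: [utr3, cds, utr5]}
#' outdir: results/pipeline
#' ```
#'
#' Missing thresholds take their defaults (`n_sd` 1, `down_cutoff` 0.8,
#' `pathway_p` 0.001). Every referenced file must exist at validation time;
#' thresholds outside their documented ranges are rejected naming the field.
#'
#' @param path path to the YAML config.
#' @return validated config list of class `PipelineConfig`.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$cell_lines) || !length(cfg$cell_lines))
    stopf("config: 'cell_lines' must list at least one cell line")
  for (cl in cfg$cell_lines) {
    if (is.null(cl$name)) stopf("config: every cell line needs a 'name'")
    for (f in c("matrix", "design", "probe_map")) {
      if (is.null(cl[[f]]))
        stopf("config: cell line '%s' is missing '%s'", cl$name, f)
      if (!file.exists(cl[[f]]))
        stopf("config: cell line '%s': %s file not found: %s", cl$name, f, cl[[f]])
    }
  }
  for (f in c("fasta", "gmt")) {
    if (is.null(cfg[[f]])) stopf("config: '%s' is required", f)
    if (!file.exists(cfg[[f]])) stopf("config: %s file not found: %s", f, cfg[[f]])
  }
  if (is.null(cfg$mirna)) stopf("config: 'mirna' (mature miRNA sequence) is required")
  if (!grepl("^[ACGUacgu]{7,}$", cfg$mirna))
    stopf("config: 'mirna' must be an RNA string of length >= 7")

  th <- cfg$thresholds %||% list()
  th$n_sd <- th$n_sd %||% 1
  th$down_cutoff <- th$down_cutoff %||% 0.8
  th$pathway_p <- th$pathway_p %||% 0.001
  check_scalar(th$n_sd, "n_sd", lower = 0)
  check_scalar(th$down_cutoff, "down_cutoff", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_scalar(th$pathway_p, "pathway_p", lower = 0, upper = 1,
               strict_lower = TRUE)
  cfg$thresholds <- th

  hx <- cfg$hexamer %||% list()
  hx$n_sims <- hx$n_sims %||% 1000
  hx$rng_seed <- hx$rng_seed %||% 1
  hx$regions <- unlist(hx$regions) %||% REGIONS
  check_scalar(hx$n_sims, "hexamer n_sims", lower = 100, integer = TRUE)
  check_scalar(hx$rng_seed, "hexamer rng_seed", integer = TRUE)
  if (!all(hx$regions %in% REGIONS))
    stopf("config: hexamer regions must be among %s", paste(REGIONS, collapse = ", "))
  cfg$hexamer <- hx

  bg <- cfg$expression_background %||% list(quantile = 0.05)
  if (!is.null(bg$quantile))
    check_scalar(bg$quantile, "expression_background quantile", lower = 0, upper = 1)
  if (!is.null(bg$absolute))
    check_scalar(bg$absolute, "expression_background absolute", lower = 0)
  cfg$expression_background <- bg

  cfg$outdir <- cfg$outdir %||% "pipeline_output"
  structure(cfg, class = "PipelineConfig")
}

#' @noRd
stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full pull-down analysis pipeline
#'
#' Stage order mirrors the analysis: per cell line, enrichment-ratio hit
#' calling, then input-arm down-regulation calling; cross-cell-line hit
#' overlap; CDF/KS comparison of fold changes for the hit and overlap sets
#' against all expressed genes; positional hexamer Monte-Carlo scan for the
#' hit, down and overlap sets; hypergeometric pathway enrichment with the
#' pathway-overlap network. All tables are written under `config$outdir`
#' together with a run manifest (versions, seeds, thresholds); reruns with
#' the same config and seeds give byte-identical outputs.
#'
#' @param config a [validate_config()] result (or path to a config YAML).
#' @return invisibly, a list with the per-cell-line tables, gene sets,
#'   comparisons, hexamer grid, pathway results and networks, plus the
#'   manifest.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- validate_config(config)
  stopifnot(inherits(config, "PipelineConfig"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  th <- config$thresholds

  seqs <- stage("sequences", read_region_fasta(config$fasta))

  per_cl <- list()
  for (cl in config$cell_lines) {
    nm <- cl$name
    res <- stage(paste0("expression:", nm), {
      pm <- read_matrix(cl$matrix, cl$design, cl$probe_map)
      bg <- config$expression_background
      flags <- if (!is.null(bg$absolute)) flag_expressed(pm, background = bg$absolute)
               else flag_expressed(pm, bg_quantile = bg$quantile)
      list(pm = pm, flags = flags)
    })
    enr <- stage(paste0("enrichment:", nm), {
      tab <- enrichment_ratio(res$pm, res$flags, cell_line = nm)
      thr <- fit_background(tab, n_sd = th$n_sd)
      hits <- call_hits(tab, thr, label = paste0("hits_", nm))
      write_enrichment_table(tab, thr, file.path(outdir, paste0("enrichment_", nm, ".tsv")))
      write_gene_list(hits, file.path(outdir, paste0("hits_", nm, ".txt")))
      list(table = tab, threshold = thr, hits = hits)
    })
    dn <- stage(paste0("downregulation:", nm), {
      fc <- fold_change(res$pm, res$flags, cell_line = nm)
      down <- call_down(fc, cutoff = th$down_cutoff, label = paste0("down_", nm))
      write_fold_change_table(fc, th$down_cutoff,
                              file.path(outdir, paste0("fold_change_", nm, ".tsv")))
      write_gene_list(down, file.path(outdir, paste0("down_", nm, ".txt")))
      list(fc = fc, down = down)
    })
    per_cl[[nm]] <- c(res, enr, dn)
  }

  cls <- names(per_cl)
  ovl <- NULL
  if (length(cls) >= 2L) {
    ovl <- stage("overlap", {
      o <- overlap(per_cl[[cls[1]]]$hits, per_cl[[cls[2]]]$hits)
      o$label <- "overlap"
      rep <- overlap_report(per_cl[[cls[1]]]$hits, per_cl[[cls[2]]]$hits)
      write_tsv(rep, file.path(outdir, "overlap_report.tsv"))
      write_gene_list(o, file.path(outdir, "overlap_hits.txt"))
      o
    })
  }

  comparisons <- stage("ks_comparisons", {
    rows <- list()
    for (nm in cls) {
      fc <- per_cl[[nm]]$fc
      expressed <- gene_set(fc$gene_id, label = paste0("expressed_", nm))
      sets <- list(per_cl[[nm]]$hits, per_cl[[nm]]$down)
      if (!is.null(ovl)) sets <- c(sets, list(ovl))
      cmp <- cdf_compare(fc, sets, expressed)
      cdf <- cdf_table(fc, c(sets, list(expressed)))
      write_tsv(cdf, file.path(outdir, paste0("cdf_", nm, ".tsv")))
      rows[[nm]] <- cmp
    }
    all <- do.call(rbind, rows)
    write_tsv(all, file.path(outdir, "ks_comparisons.tsv"))
    all
  })

  hex <- stage("hexamer", {
    universe <- unique(unlist(lapply(per_cl, function(x) x$table$gene_id)))
    background <- gene_set(universe, label = "expressed")
    sets <- unlist(lapply(per_cl, function(x) list(x$hits, x$down)),
                   recursive = FALSE)
    if (!is.null(ovl)) sets <- c(sets, list(ovl))
    grid <- hexamer_scan_all(config$mirna, sets, background, seqs,
                             regions = config$hexamer$regions,
                             n_sims = config$hexamer$n_sims,
                             rng_seed = config$hexamer$rng_seed)
    write_tsv(grid, file.path(outdir, "hexamer_grid.tsv"))
    grid
  })

  pw <- stage("pathways", {
    universe <- unique(unlist(lapply(per_cl, function(x) x$table$gene_id)))
    pathways <- read_gmt(config$gmt, universe = universe)
    sets <- unlist(lapply(per_cl, function(x) list(x$hits, x$down)),
                   recursive = FALSE)
    if (!is.null(ovl)) sets <- c(sets, list(ovl))
    out <- list()
    for (s in sets) {
      res <- suppressWarnings(enrich_pathways(s, pathways, p_cut = th$pathway_p))
      write_tsv(res, file.path(outdir, paste0("pathways_", s$label, ".tsv")))
      net <- build_network(res, s, pathways, p_cut = th$pathway_p)
      write_network(net, file.path(outdir, paste0("network_", s$label, ".sif")),
                    file.path(outdir, paste0("network_", s$label, "_nodes.tsv")))
      out[[s$label]] <- list(results = res, network = net)
    }
    out
  })

  manifest <- list(package = "mirpulldown",
                   version = as.character(packageVersion("mirpulldown")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   thresholds = th,
                   hexamer = config$hexamer,
                   expression_background = config$expression_background,
                   mirna = config$mirna,
                   cell_lines = lapply(config$cell_lines, function(cl)
                     cl[c("name", "matrix", "design", "probe_map")]),
                   fasta = config$fasta, gmt = config$gmt)
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))

  invisible(list(cell_lines = per_cl, overlap = ovl, comparisons = comparisons,
                 hexamer = hex, pathways = pw, manifest = manifest))
}
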