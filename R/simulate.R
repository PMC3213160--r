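#' Configuration for the synthetic pull-down experiment generator
#'
#' Defines the statistical structure the analysis assumes: log-normal
#' replicate noise on a four-arm design (pull-down and input under test- and
#' control-miRNA transfection), a planted true-target set with multiplicative
#' pull-down enrichment and input-mRNA knockdown, nonspecific bead capture
#' coupled to abundance, and elevated seed-match density in target 3'UTRs.
#'
#' @param n_genes number of genes.
#' @param probes_per_gene probes per gene: a single count or a `c(min, max)`
#'   range sampled uniformly.
#' @param n_replicates biological replicates per arm.
#' @param target_fraction fraction of genes that are true targets, in [0, 1].
#' @param enrichment_effect multiplicative pull-down enrichment of targets
#'   (fold, > 1).
#' @param knockdown_effect input-mRNA level of targets as a fraction of
#'   control (in (0, 1)).
#' @param noise_sd SD of the log2-scale replicate noise per measurement.
#' @param background_affinity exponent coupling nonspecific bead capture to
#'   cellular abundance (1 = proportional).
#' @param seed_density_target,seed_density_background expected planted
#'   seed-site count per kb of 3'UTR for targets / non-targets.
#' @param utr_length_dist named list `utr5`, `cds`, `utr3`, each
#'   `c(meanlog, sdlog)` of a log-normal length distribution (bp).
#' @param min_region_length minimum region length in bp after rounding.
#' @param n_pathways,pathway_size_dist,target_enriched_pathway_fraction
#'   pathway collection shape: number of pathways, `c(min, max)` size range,
#'   and the fraction of pathways that oversample target genes.
#' @param mirna mature miRNA sequence (RNA alphabet) whose seed sites are
#'   planted; default is mature hsa-miR-34a-5p.
#' @param abundance_meanlog2,abundance_sdlog2 log2-scale mean and SD of
#'   baseline transcript abundance.
#' @param probe_effect_sd log2-scale SD of the per-probe affinity multiplier
#'   (constant across samples, so it cancels in every ratio).
#' @param rng_seed integer seed; identical config + seed reproduces outputs
#'   byte for byte.
#' @return validated list of class `SimulationConfig`.
#' @export
simulation_config <- function(n_genes = 2000,
                              probes_per_gene = c(1, 3),
                              n_replicates = 2,
                              target_fraction = 0.1,
                              enrichment_effect = 4,
                              knockdown_effect = 0.7,
                              noise_sd = 0.5,
                              background_affinity = 1,
                              seed_density_target = 5,
                              seed_density_background = 1,
                              utr_length_dist = list(utr5 = c(meanlog = log(200), sdlog = 0.4),
                                                     cds = c(meanlog = log(1300), sdlog = 0.4),
                                                     utr3 = c(meanlog = log(1000), sdlog = 0.6)),
                              min_region_length = 30,
                              n_pathways = 50,
                              pathway_size_dist = c(10, 100),
                              target_enriched_pathway_fraction = 0.2,
                              mirna = "UGGCAGUGUCUUAGCUGGUUGU",
                              abundance_meanlog2 = 7,
                              abundance_sdlog2 = 2,
                              probe_effect_sd = 0.25,
                              rng_seed = 1) {
  check_scalar(n_genes, "n_genes", lower = 1, integer = TRUE)
  if (!is.numeric(probes_per_gene) || !length(probes_per_gene) %in% 1:2 ||
      any(probes_per_gene < 1) || any(probes_per_gene != round(probes_per_gene)))
    stopf("invalid configuration: 'probes_per_gene' must be a positive count or c(min, max) range")
  if (length(probes_per_gene) == 2L && probes_per_gene[1] > probes_per_gene[2])
    stopf("invalid configuration: 'probes_per_gene' range must have min <= max")
  check_scalar(n_replicates, "n_replicates", lower = 1, integer = TRUE)
  check_scalar(target_fraction, "target_fraction", lower = 0, upper = 1)
  check_scalar(enrichment_effect, "enrichment_effect", lower = 1, strict_lower = TRUE)
  check_scalar(knockdown_effect, "knockdown_effect", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  check_scalar(background_affinity, "background_affinity", lower = 0)
  check_scalar(seed_density_target, "seed_density_target", lower = 0)
  check_scalar(seed_density_background, "seed_density_background", lower = 0)
  if (!is.list(utr_length_dist) || !all(REGIONS %in% names(utr_length_dist)))
    stopf("invalid configuration: 'utr_length_dist' must name utr5, cds and utr3")
  for (r in REGIONS) if (length(utr_length_dist[[r]]) != 2L)
    stopf("invalid configuration: 'utr_length_dist$%s' must be c(meanlog, sdlog)", r)
  check_scalar(min_region_length, "min_region_length", lower = 6, integer = TRUE)
  check_scalar(n_pathways, "n_pathways", lower = 1, integer = TRUE)
  if (length(pathway_size_dist) != 2L || any(pathway_size_dist < 1) ||
      pathway_size_dist[1] > pathway_size_dist[2])
    stopf("invalid configuration: 'pathway_size_dist' must be c(min, max) with min <= max")
  check_scalar(target_enriched_pathway_fraction, "target_enriched_pathway_fraction",
               lower = 0, upper = 1)
  mirna <- toupper(as.character(mirna))
  if (!grepl("^[ACGU]{7,}$", mirna))
    stopf("invalid configuration: 'mirna' must be an RNA string of length >= 7")
  check_scalar(probe_effect_sd, "probe_effect_sd", lower = 0)
  check_scalar(rng_seed, "rng_seed", integer = TRUE)

  structure(list(n_genes = as.integer(n_genes),
                 probes_per_gene = as.integer(probes_per_gene),
                 n_replicates = as.integer(n_replicates),
                 target_fraction = target_fraction,
                 enrichment_effect = enrichment_effect,
                 knockdown_effect = knockdown_effect,
                 noise_sd = noise_sd,
                 background_affinity = background_affinity,
                 seed_density_target = seed_density_target,
                 seed_density_background = seed_density_background,
                 utr_length_dist = utr_length_dist,
                 min_region_length = as.integer(min_region_length),
                 n_pathways = as.integer(n_pathways),
                 pathway_size_dist = as.integer(pathway_size_dist),
                 target_enriched_pathway_fraction = target_enriched_pathway_fraction,
                 mirna = mirna,
                 abundance_meanlog2 = abundance_meanlog2,
                 abundance_sdlog2 = abundance_sdlog2,
                 probe_effect_sd = probe_effect_sd,
                 rng_seed = as.integer(rng_seed)),
            class = "SimulationConfig")
}

#' Simulate probe-level four-arm expression data with planted targets
#'
#' Expression is generated on the log2 scale (Gaussian replicate noise) and
#' exponentiated, matching the log-normal background the hit calling assumes.
#' Expected arm levels per gene with baseline abundance `a`, knockdown `kd`
#' and enrichment `e` (both 1 for non-targets) are: input_control = `a`,
#' input_test = `kd * a`, and for the pull-down arms a nonspecific bead
#' capture level `b = a^background_affinity` common to both: pulldown_control
#' = `b`, pulldown_test = `e * kd * b`. The input normalization of the
#' enrichment ratio therefore cancels the abundance-dependent background
#' exactly in expectation: the expected ratio is `e` for targets and 1
#' otherwise, and the expected input fold change is `kd`. Per-probe affinity
#' multipliers are constant across samples and cancel in every ratio.
#'
#' @param config a [simulation_config()].
#' @param cell_line label written into the design (default `"CL1"`).
#' @param targets optional character vector of gene ids (`g00001` style) to
#'   plant as targets, overriding random selection — used to give two
#'   simulated cell lines a shared target set.
#' @return list with `matrix` (a [probe_matrix()]) and `truth` (data.frame
#'   `gene_id`, `is_target`, `planted_enrichment`, `planted_knockdown`).
#' @export
simulate_expression <- function(config, cell_line = "CL1", targets = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$rng_seed)
  n <- config$n_genes
  gene_id <- sprintf("g%05d", seq_len(n))

  if (is.null(targets)) {
    n_targets <- round(config$target_fraction * n)
    is_target <- rep(FALSE, n)
    if (n_targets > 0) is_target[sample.int(n, n_targets)] <- TRUE
  } else {
    if (!all(targets %in% gene_id))
      stopf("'targets' contains gene ids outside the simulated genes")
    is_target <- gene_id %in% targets
  }
  e <- ifelse(is_target, config$enrichment_effect, 1)
  kd <- ifelse(is_target, config$knockdown_effect, 1)

  a <- 2^rnorm(n, config$abundance_meanlog2, config$abundance_sdlog2)
  # bead capture coupled to abundance, centered on the abundance scale
  b <- 2^(config$background_affinity * (log2(a) - config$abundance_meanlog2) +
            config$abundance_meanlog2)

  ppg <- if (length(config$probes_per_gene) == 1L)
    rep(config$probes_per_gene, n)
  else
    sample(seq(config$probes_per_gene[1], config$probes_per_gene[2]), n, replace = TRUE)
  gi <- rep(seq_len(n), ppg)
  n_probes <- length(gi)
  probe_id <- sprintf("p%07d", seq_len(n_probes))
  affinity <- 2^rnorm(n_probes, 0, config$probe_effect_sd)

  arms <- expand.grid(arm = c("pulldown", "input"), mirna = c("test", "control"),
                      replicate = seq_len(config$n_replicates),
                      stringsAsFactors = FALSE)
  arms <- arms[order(arms$replicate, arms$arm, arms$mirna), ]
  design <- data.frame(sample_id = sprintf("%s_%s_%s_r%d", cell_line,
                                           substr(arms$arm, 1, 2), arms$mirna,
                                           arms$replicate),
                       arm = arms$arm, mirna = arms$mirna,
                       replicate = arms$replicate, cell_line = cell_line,
                       row.names = NULL)

  expected_for <- function(arm, mirna) {
    base <- switch(paste(arm, mirna),
                   "input control" = a,
                   "input test" = kd * a,
                   "pulldown control" = b,
                   "pulldown test" = e * kd * b)
    base[gi] * affinity
  }
  values <- matrix(NA_real_, n_probes, nrow(design),
                   dimnames = list(probe_id, design$sample_id))
  for (j in seq_len(nrow(design))) {
    mu <- expected_for(design$arm[j], design$mirna[j])
    values[, j] <- mu * 2^rnorm(n_probes, 0, config$noise_sd)
  }

  pm <- probe_matrix(values, design,
                     data.frame(probe_id = probe_id, gene_id = gene_id[gi]))
  truth <- data.frame(gene_id = gene_id, is_target = is_target,
                      planted_enrichment = e, planted_knockdown = kd)
  list(matrix = pm, truth = truth)
}

#' Simulate region-annotated transcript sequences with planted seed sites
#'
#' Region lengths are log-normal; sequence composition is uniform A/C/G/T
#' outside planted sites. Seed sites (the DNA reverse complement of the
#' miRNA's nt 2-7 window) are planted in the 3'UTR as a Poisson process at
#' `seed_density_target` per kb for true targets and
#' `seed_density_background` otherwise; planted sites never overlap each
#' other (rejection sampling), so the recorded planted counts are exact.
#'
#' @param config a [simulation_config()].
#' @param truth truth labels from [simulate_expression()].
#' @return list with `seqs` (a [region_sequence_set()]) and `truth` extended
#'   with `planted_seed_sites_utr3` (planted counts for `utr5`/`cds` are 0 by
#'   construction).
#' @export
simulate_sequences <- function(config, truth) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (is.null(truth) || nrow(truth) == 0L) stopf("empty truth label set")
  set.seed(config$rng_seed + 101L)
  n <- nrow(truth)
  site <- seed_site(config$mirna)
  w <- nchar(site)

  lens <- lapply(REGIONS, function(r) {
    p <- config$utr_length_dist[[r]]
    pmax(config$min_region_length,
         as.integer(round(exp(rnorm(n, p[[1]], p[[2]])))))
  })
  names(lens) <- REGIONS

  random_seqs <- function(len) {
    big <- paste(sample(c("A", "C", "G", "T"), sum(len), replace = TRUE),
                 collapse = "")
    ends <- cumsum(len)
    substring(big, ends - len + 1L, ends)
  }
  out <- lapply(lens, random_seqs)

  dens <- ifelse(truth$is_target, config$seed_density_target,
                 config$seed_density_background)
  planted <- rpois(n, dens * lens$utr3 / 1000)
  for (i in which(planted > 0L)) {
    len <- lens$utr3[i]
    max_sites <- (len %/% w)
    planted[i] <- min(planted[i], max_sites)
    chosen <- integer(0)
    attempts <- 0L
    while (length(chosen) < planted[i] && attempts < 100L * planted[i]) {
      pos <- sample.int(len - w + 1L, 1L)
      if (all(abs(pos - chosen) >= w)) chosen <- c(chosen, pos)
      attempts <- attempts + 1L
    }
    planted[i] <- length(chosen)
    s <- strsplit(out$utr3[i], "", fixed = TRUE)[[1]]
    for (pos in chosen) s[pos:(pos + w - 1L)] <- strsplit(site, "", fixed = TRUE)[[1]]
    out$utr3[i] <- paste(s, collapse = "")
  }

  seqs <- region_sequence_set(
    utr5 = setNames(out$utr5, truth$gene_id),
    cds = setNames(out$cds, truth$gene_id),
    utr3 = setNames(out$utr3, truth$gene_id),
    provenance = data.frame(gene_id = truth$gene_id, transcript_id = truth$gene_id))
  truth$planted_seed_sites_utr3 <- planted
  list(seqs = seqs, truth = truth)
}

#' Simulate a pathway collection with a target-enriched subset
#'
#' A stated fraction of pathways oversample true-target genes (sampling
#' weight 8:1 in favor of targets, without replacement), so hypergeometric
#' enrichment is recoverable; the remaining pathways sample genes uniformly.
#'
#' @param config a [simulation_config()].
#' @param truth truth labels from [simulate_expression()].
#' @return a [pathway_collection()] over all simulated genes.
#' @export
simulate_pathways <- function(config, truth) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (is.null(truth) || nrow(truth) == 0L) stopf("empty truth label set")
  if (config$pathway_size_dist[2] > config$n_genes)
    stopf("invalid configuration: 'pathway_size_dist' max (%d) exceeds n_genes (%d)",
          config$pathway_size_dist[2], config$n_genes)
  set.seed(config$rng_seed + 202L)
  np <- config$n_pathways
  sizes <- sample(seq(config$pathway_size_dist[1], config$pathway_size_dist[2]),
                  np, replace = TRUE)
  n_enriched <- round(config$target_enriched_pathway_fraction * np)
  enriched <- seq_len(np) <= n_enriched
  wt <- ifelse(truth$is_target, 8, 1)
  sets <- lapply(seq_len(np), function(i) {
    if (enriched[i] && any(truth$is_target))
      sample(truth$gene_id, sizes[i], prob = wt)
    else
      sample(truth$gene_id, sizes[i])
  })
  names(sets) <- sprintf("PW%03d", seq_len(np))
  desc <- setNames(ifelse(enriched, "synthetic target-enriched pathway",
                          "synthetic background pathway"), names(sets))
  pathway_collection(sets, universe = truth$gene_id, descriptions = desc)
}

#' Write a simulated experiment to plain-text files
#'
#' Emits the external formats the pipeline readers consume: probe matrix TSV,
#' sample design TSV, probe map TSV, truth-label TSV, region FASTA and
#' pathway GMT. Same config + seed gives byte-identical files.
#'
#' @param config a [simulation_config()].
#' @param dir output directory (created if needed).
#' @param cell_line design label.
#' @return named list of the written paths, invisibly; the simulated objects
#'   are returned in the `objects` element.
#' @export
write_simulation <- function(config, dir, cell_line = "CL1") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_expression(config, cell_line = cell_line)
  sq <- simulate_sequences(config, sim$truth)
  pw <- simulate_pathways(config, sim$truth)

  paths <- list(matrix = file.path(dir, "matrix.tsv"),
                design = file.path(dir, "design.tsv"),
                probe_map = file.path(dir, "probe_map.tsv"),
                truth = file.path(dir, "truth.tsv"),
                fasta = file.path(dir, "sequences.fasta"),
                gmt = file.path(dir, "pathways.gmt"))
  m <- sim$matrix
  write_tsv(data.frame(probe_id = rownames(m$values), m$values,
                       check.names = FALSE), paths$matrix)
  write_tsv(m$design, paths$design)
  write_tsv(m$probe_map, paths$probe_map)
  write_tsv(sq$truth, paths$truth)
  write_region_fasta(sq$seqs, paths$fasta)
  write_gmt(pw, paths$gmt)
  paths$objects <- list(matrix = m, truth = sq$truth, seqs = sq$seqs, pathways = pw)
  invisible(paths)
}
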