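#' Positional hexamer windows of a mature miRNA and their mRNA target sites
#'
#' Slides a 6-nt window along the mature miRNA (5' to 3', 1-based positions)
#' and reports, for each start, the miRNA hexamer and the DNA sequence an mRNA
#' must contain to base-pair with it perfectly: the reverse complement of the
#' window, written 5' to 3' with U transcribed to T. The canonical seed window
#' starts at nt 2 (seed = nt 2-7).
#'
#' @param mirna mature miRNA sequence, RNA alphabet (A/C/G/U), length >= 7;
#'   character string or `Biostrings::RNAString`.
#' @return data.frame: `start` (1-based window start on the miRNA),
#'   `mirna_hexamer` (RNA), `site` (DNA target site).
#' @export
positional_hexamers <- function(mirna) {
  mirna <- toupper(as.character(mirna))
  if (!grepl("^[ACGU]+$", mirna))
    stopf("miRNA sequence must use the RNA alphabet A/C/G/U (got '%s')", mirna)
  L <- nchar(mirna)
  if (L < 6L) stopf("miRNA must be at least 6 nt (got %d)", L)
  starts <- seq_len(L - 5L)
  win <- substring(mirna, starts, starts + 5L)
  site <- vapply(win, function(w) {
    as.character(DNAString(reverseComplement(RNAString(w))))
  }, character(1), USE.NAMES = FALSE)
  data.frame(start = starts, mirna_hexamer = win, site = site)
}

#' The DNA seed-match site of a miRNA (reverse complement of nt 2-7)
#'
#' @param mirna mature miRNA sequence (RNA alphabet).
#' @return 6-nt DNA string.
#' @export
seed_site <- function(mirna) {
  hx <- positional_hexamers(mirna)
  if (nrow(hx) < 2L) stopf("miRNA too short for a seed window at nt 2")
  hx$site[hx$start == 2L]
}

#' Count exact occurrences of a hexamer site in sequences
#'
#' Occurrences are counted overlapping (e.g. `AAAAAA` occurs 3 times in
#' `AAAAAAAA`); matching is case-insensitive and positions containing N never
#' match.
#'
#' @param seq a character vector, `DNAString` or `DNAStringSet`.
#' @param site DNA hexamer (any k-mer works).
#' @return integer vector of counts, one per input sequence.
#' @export
count_matches <- function(seq, site) {
  site <- toupper(as.character(site))
  if (!grepl("^[ACGT]+$", site)) stopf("site must be a DNA string (A/C/G/T)")
  if (is.character(seq)) seq <- DNAStringSet(toupper(seq))
  if (is(seq, "DNAString")) seq <- DNAStringSet(list(seq))
  as.integer(vcountPattern(site, seq, fixed = TRUE))
}

#' Pooled per-kb hexamer frequency of a gene set in one region
#'
#' Total exact (overlapping) matches across the set's region sequences
#' divided by the total region length in kb. Genes without a sequence for the
#' region are excluded and counted in the `n_missing` attribute.
#'
#' @param genes a [gene_set()] or character vector of gene ids.
#' @param seqs a [region_sequence_set()].
#' @param region one of `"utr5"`, `"cds"`, `"utr3"`.
#' @param site DNA hexamer target site.
#' @return matches per kb (numeric scalar) with attributes `n_genes` (genes
#'   with sequence), `n_missing`, `total_kb`, `total_matches`.
#' @export
set_frequency <- function(genes, seqs, region, site) {
  if (inherits(genes, "GeneSet")) genes <- genes$members
  region <- match.arg(region, REGIONS)
  s <- seqs[[region]]
  have <- genes[genes %in% names(s)]
  n_missing <- length(genes) - length(have)
  if (!length(have)) stopf("no gene in the set has a sequence for region '%s'", region)
  sub <- s[have]
  kb <- sum(Biostrings::width(sub)) / 1000
  if (kb == 0) stopf("total sequence length for region '%s' is zero", region)
  m <- sum(count_matches(sub, site))
  structure(m / kb, n_genes = length(have), n_missing = n_missing,
            total_kb = kb, total_matches = m)
}

#' Per-gene match counts and lengths, precomputed for fast resampling
#' @noRd
region_counts <- function(gene_ids, seqs, region, site) {
  s <- seqs[[region]]
  have <- gene_ids[gene_ids %in% names(s)]
  sub <- s[have]
  list(genes = have,
       counts = count_matches(sub, site),
       widths = Biostrings::width(sub),
       n_missing = length(gene_ids) - length(have))
}

#' Monte-Carlo enrichment of a hexamer site in a gene set
#'
#' The observed statistic is the pooled per-kb frequency of `site` in the
#' set's `region` sequences. The null is built from `n_sims` random gene sets
#' of the same size drawn without replacement from the background (which
#' normally contains the test set: all expressed genes on the platform). The
#' empirical two-tailed p doubles the smaller one-sided tail, each computed
#' with a +1 pseudocount: `P_ge = (1 + #\{null >= obs\})/(n_sims + 1)`, so the
#' attainable floor is `2/(n_sims + 1)`. When the empirical p reaches 1e-4 or
#' its resampling floor, a Gaussian tail extrapolation ([tail_extrapolate()])
#' is reported alongside (never replacing) the empirical value.
#'
#' @param gene_set a [gene_set()] (the test list).
#' @param background a [gene_set()] or character vector of background gene
#'   ids; must be at least as large as `gene_set`.
#' @param seqs a [region_sequence_set()].
#' @param region one of `"utr5"`, `"cds"`, `"utr3"`.
#' @param site DNA hexamer target site.
#' @param n_sims number of Monte-Carlo draws (>= 100).
#' @param rng_seed optional integer seed; when given, results are reproducible.
#' @return one-row data.frame of class `HexamerResult`: `region`, `site`,
#'   `set_label`, `n_set`, `set_freq_per_kb`, `bg_freq_per_kb`, `fold`,
#'   `p_empirical`, `p_tail`, `n_sims`.
#' @export
mc_enrichment <- function(gene_set, background, seqs, region, site,
                          n_sims = 1000, rng_seed = NULL) {
  check_scalar(n_sims, "n_sims", lower = 100, integer = TRUE)
  if (inherits(gene_set, "GeneSet")) {
    set_label <- gene_set$label; members <- gene_set$members
  } else {
    set_label <- "set"; members <- as.character(gene_set)
  }
  bg_ids <- if (inherits(background, "GeneSet")) background$members else as.character(background)
  if (length(members) > length(bg_ids))
    stopf("gene set (%d) is larger than the background (%d)",
          length(members), length(bg_ids))
  if (!is.null(rng_seed)) set.seed(rng_seed)

  region <- match.arg(region, REGIONS)
  bg <- region_counts(bg_ids, seqs, region, site)
  if (!length(bg$genes)) stopf("no background gene has a sequence for region '%s'", region)
  obs <- as.numeric(set_frequency(members, seqs, region, site))
  # null sets are size-matched to the genes that actually contribute sequence
  k <- sum(members %in% names(seqs[[region]]))

  null <- replicate(n_sims, {
    idx <- sample.int(length(bg$genes), k)
    sum(bg$counts[idx]) / (sum(bg$widths[idx]) / 1000)
  })
  n_ge <- sum(null >= obs); n_le <- sum(null <= obs)
  p_ge <- (1 + n_ge) / (n_sims + 1)
  p_le <- (1 + n_le) / (n_sims + 1)
  p_emp <- min(1, 2 * min(p_ge, p_le))
  bg_freq <- sum(bg$counts) / (sum(bg$widths) / 1000)
  # tail extrapolation engages at/below 1e-4 or when the empirical p sits at
  # its resampling floor (no null value as extreme as the observation)
  at_floor <- min(n_ge, n_le) == 0L
  p_tail <- if (p_emp <= 1e-4 || at_floor) tail_extrapolate(obs, null) else NA_real_

  out <- data.frame(region = region, site = site, set_label = set_label,
                    n_set = k,
                    set_freq_per_kb = obs, bg_freq_per_kb = bg_freq,
                    fold = if (bg_freq > 0) obs / bg_freq else NA_real_,
                    p_empirical = p_emp, p_tail = p_tail, n_sims = n_sims)
  class(out) <- c("HexamerResult", "data.frame")
  out
}

#' Gaussian tail extrapolation of a Monte-Carlo p-value
#'
#' When the observed frequency lies beyond the resolution of the Monte-Carlo
#' null (empirical p at its floor), a Gaussian is fitted to the null sample
#' (mean and SD) and the two-tailed normal tail probability of the observed
#' value is returned.
#'
#' @param observed observed statistic.
#' @param null_sample numeric vector of null statistics.
#' @return two-tailed Gaussian p; `NA` (with a warning) when the null sample
#'   is degenerate (SD = 0).
#' @export
tail_extrapolate <- function(observed, null_sample) {
  m <- mean(null_sample); s <- sd(null_sample)
  if (!is.finite(s) || s == 0) {
    warnf("degenerate Monte-Carlo null (SD = 0); tail p is NA")
    return(NA_real_)
  }
  2 * pnorm(-abs(observed - m) / s)
}

#' Positional hexamer enrichment scan over regions and gene sets
#'
#' Runs [mc_enrichment()] for every hexamer window of the miRNA, every region
#' and every gene set: the full grid has (L-5) x #regions x #sets rows. Draws
#' are taken from a single seeded RNG stream over a fixed iteration order
#' (set, region, window), so results are reproducible given `rng_seed`.
#'
#' @param mirna mature miRNA sequence (RNA alphabet).
#' @param gene_sets list of [gene_set()]s (a single one is accepted).
#' @param background background [gene_set()] or character vector (normally
#'   all expressed genes, which includes the test sets).
#' @param seqs a [region_sequence_set()].
#' @param regions regions to scan (default all three).
#' @param n_sims Monte-Carlo draws per cell (>= 100).
#' @param rng_seed integer seed for the scan.
#' @return data.frame: `mirna`, `hexamer_start`, `site`, `region`,
#'   `set_label`, `n_set`, `set_freq_per_kb`, `bg_freq_per_kb`, `fold`,
#'   `p_empirical`, `p_tail`, `n_sims`, `seed`.
#' @export
hexamer_scan_all <- function(mirna, gene_sets, background, seqs,
                             regions = REGIONS, n_sims = 1000, rng_seed = 1) {
  if (inherits(gene_sets, "GeneSet")) gene_sets <- list(gene_sets)
  regions <- match.arg(regions, REGIONS, several.ok = TRUE)
  hx <- positional_hexamers(mirna)
  set.seed(rng_seed)
  rows <- list()
  for (s in gene_sets) for (r in regions) for (i in seq_len(nrow(hx))) {
    res <- mc_enrichment(s, background, seqs, r, hx$site[i],
                         n_sims = n_sims, rng_seed = NULL)
    res$hexamer_start <- hx$start[i]
    rows[[length(rows) + 1L]] <- res
  }
  out <- do.call(rbind, rows)
  out$mirna <- toupper(as.character(mirna))
  out$seed <- rng_seed
  out[, c("mirna", "hexamer_start", "site", "region", "set_label", "n_set",
          "set_freq_per_kb", "bg_freq_per_kb", "fold", "p_empirical",
          "p_tail", "n_sims", "seed")]
}
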