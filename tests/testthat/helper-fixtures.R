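# Fixtures are built in code; no data files are shipped.

# Four-arm design for one cell line with n replicates
toy_design <- function(n_reps = 2, cell_line = "CL1") {
  grid <- expand.grid(arm = c("pulldown", "input"), mirna = c("test", "control"),
                      replicate = seq_len(n_reps), stringsAsFactors = FALSE)
  data.frame(sample_id = sprintf("%s_%s_%s_r%d", cell_line,
                                 substr(grid$arm, 1, 2), grid$mirna, grid$replicate),
             arm = grid$arm, mirna = grid$mirna, replicate = grid$replicate,
             cell_line = cell_line)
}

# ProbeMatrix from explicit per-arm intensity vectors (one replicate);
# each argument is a vector over probes
arm_matrix <- function(pd_test, pd_control, in_test, in_control,
                       probe_ids = sprintf("p%02d", seq_along(pd_test)),
                       gene_ids = probe_ids, cell_line = "CL1") {
  design <- toy_design(1, cell_line)
  v <- matrix(NA_real_, length(pd_test), 4,
              dimnames = list(probe_ids, design$sample_id))
  pick <- function(arm, mirna) design$sample_id[design$arm == arm & design$mirna == mirna]
  v[, pick("pulldown", "test")] <- pd_test
  v[, pick("pulldown", "control")] <- pd_control
  v[, pick("input", "test")] <- in_test
  v[, pick("input", "control")] <- in_control
  probe_matrix(v, design, data.frame(probe_id = probe_ids, gene_id = gene_ids))
}

# A 5-gene, 8-probe, 2-replicate fixture with fixed arbitrary intensities
toy_fixture <- function() {
  set.seed(42)
  gene_ids <- c("gA", "gA", "gB", "gC", "gC", "gC", "gD", "gE")
  probe_ids <- sprintf("p%02d", 1:8)
  design <- toy_design(2)
  v <- matrix(round(2^runif(8 * 8, 2, 10), 4), 8, 8,
              dimnames = list(probe_ids, design$sample_id))
  list(matrix = probe_matrix(v, design,
                             data.frame(probe_id = probe_ids, gene_id = gene_ids)),
       design = design, gene_ids = gene_ids, probe_ids = probe_ids, values = v)
}

# Spreadsheet-style oracle for the enrichment stage: explicit loops over
# probes, replicates and genes, independent of the package's vectorized path
oracle_ratio_table <- function(values, design, gene_ids,
                               kind = c("enrichment", "fold_change")) {
  kind <- match.arg(kind)
  reps <- sort(unique(design$replicate))
  col_of <- function(arm, mirna, r)
    design$sample_id[design$arm == arm & design$mirna == mirna & design$replicate == r]
  per_probe <- numeric(nrow(values))
  for (i in seq_len(nrow(values))) {
    rr <- numeric(0)
    for (r in reps) {
      if (kind == "enrichment") {
        num <- values[i, col_of("pulldown", "test", r)] /
          values[i, col_of("pulldown", "control", r)]
        den <- values[i, col_of("input", "test", r)] /
          values[i, col_of("input", "control", r)]
        rr <- c(rr, num / den)
      } else {
        rr <- c(rr, values[i, col_of("input", "test", r)] /
                  values[i, col_of("input", "control", r)])
      }
    }
    per_probe[i] <- mean(rr)
  }
  out <- c()
  for (g in unique(gene_ids)) out[g] <- mean(per_probe[gene_ids == g])
  out
}

# Closed-form log2-scale SD of the arithmetic mean of n_reps lognormal
# replicate ratios (Fenton-Wilkinson moment matching); each replicate ratio
# combines four measurements, so its log2 SD is 2 * noise_sd
fw_sigma_log2 <- function(noise_sd, n_reps) {
  s2 <- (2 * noise_sd * log(2))^2
  sqrt(log(1 + (exp(s2) - 1) / n_reps)) / log(2)
}

# Closed-form normal-tail oracle for sensitivity/specificity of 1-SD hit
# calling on a two-component mixture (fraction f shifted by log2(effect)).
# With geometric replicate averaging the per-gene log2 ratio is exactly
# normal with sd 2*noise_sd/sqrt(n_reps) and the oracle is exact; for the
# arithmetic mean the Fenton-Wilkinson sd is a close approximation.
normal_tail_oracle <- function(noise_sd, n_reps, effect, f,
                               averaging = c("arithmetic", "geometric")) {
  averaging <- match.arg(averaging)
  sig <- if (averaging == "geometric") 2 * noise_sd / sqrt(n_reps)
         else fw_sigma_log2(noise_sd, n_reps)
  mu_t <- log2(effect)
  thr <- f * mu_t + sqrt(sig^2 + f * (1 - f) * mu_t^2)  # relative to null mean
  list(sensitivity = pnorm((mu_t - thr) / sig),
       specificity = pnorm(thr / sig))
}

# Brute-force two-sample KS sup-distance over all pooled data points
brute_ks_D <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
}

# Exhaustive hypergeometric upper tail by subset enumeration:
# draw all C(N, n) query subsets of 1:N, pathway = 1:K
enum_hyper_tail <- function(k, K, n, N) {
  if (n == 0) return(if (k == 0) 1 else 0)
  subsets <- utils::combn(N, n)
  overlaps <- colSums(subsets <= K)
  mean(overlaps >= k)
}

# Naive O(n*k) sliding-window overlapping match count
naive_count <- function(seq, site) {
  n <- nchar(seq); k <- nchar(site)
  if (n < k) return(0L)
  sum(vapply(seq_len(n - k + 1L),
             function(i) substr(seq, i, i + k - 1L) == site, logical(1)))
}

# Tiny RegionSequenceSet built from a named character vector per region
tiny_seqs <- function(utr3, cds = NULL, utr5 = NULL) {
  region_sequence_set(utr5 = utr5, cds = cds, utr3 = utr3)
}
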