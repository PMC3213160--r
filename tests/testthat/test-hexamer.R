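# independent reverse-complement oracle: reverse, complement, U->T
rc_oracle <- function(rna) {
  comp <- chartr("ACGU", "UGCA", rna)
  dna <- chartr("U", "T", comp)
  paste(rev(strsplit(dna, "")[[1]]), collapse = "")
}

MIR34A <- "UGGCAGUGUCUUAGCUGGUUGU"

test_that("positional hexamer windows cover the miRNA with reverse-complement DNA sites", {
  hx <- positional_hexamers("UGGCAGUGUC")
  expect_equal(nrow(hx), 5L)
  expect_equal(hx$start, 1:5)

  expect_equal(positional_hexamers("ACUGCCAAAA")$site[1], "GGCAGT")

  hx34 <- positional_hexamers(MIR34A)
  expect_equal(nrow(hx34), nchar(MIR34A) - 5L)
  for (i in seq_len(nrow(hx34)))
    expect_equal(hx34$site[i], rc_oracle(hx34$mirna_hexamer[i]))
  # the canonical seed window (nt 2-7) is always among the windows
  expect_true(2L %in% hx34$start)
  expect_equal(seed_site(MIR34A), "ACTGCC")

  expect_error(positional_hexamers("UGGXAGU"), "alphabet|A/C/G/U")
})

test_that("match counting is overlapping, case-insensitive, and N never matches", {
  expect_equal(count_matches("AAAAAAAA", "AAAAAA"), 3L)
  for (n in 6:30)
    expect_equal(count_matches(strrep("A", n), "AAAAAA"), n - 5L)
  expect_equal(count_matches("CCCCCCCC", "AAAAAA"), 0L)
  expect_equal(count_matches("aaaaaaaa", "aaaaaa"), 3L)
  expect_equal(count_matches("AAANAAAAAA", "AAAAAA"), 1L)

  set.seed(12)
  seq10k <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE), collapse = "")
  for (site in c("ACTGCC", "AAAAAA", "GCGCGC"))
    expect_equal(count_matches(seq10k, site), naive_count(seq10k, site))
})

test_that("pooled per-kb frequency is total matches over total kb", {
  # one gene, 2 kb of non-matching filler with the site planted 4 times
  filler <- strrep("C", 494)
  seq1 <- paste0(strrep(paste0("ACTGCC", filler), 4), "")
  expect_equal(nchar(seq1), 2000L)
  seqs <- tiny_seqs(utr3 = c(g1 = seq1))
  f <- set_frequency(gene_set("g1", "s"), seqs, "utr3", "ACTGCC")
  expect_equal(as.numeric(f), 2)

  # duplicating every gene leaves the pooled frequency unchanged
  seqs2 <- tiny_seqs(utr3 = c(g1 = seq1, g2 = seq1))
  f2 <- set_frequency(gene_set(c("g1", "g2"), "s"), seqs2, "utr3", "ACTGCC")
  expect_equal(as.numeric(f2), as.numeric(f))

  # genes without sequence are excluded and counted
  f3 <- set_frequency(gene_set(c("g1", "gMISSING"), "s"), seqs, "utr3", "ACTGCC")
  expect_equal(attr(f3, "n_missing"), 1L)
  expect_equal(as.numeric(f3), 2)
})

test_that("a 50-gene pooled frequency equals a brute-force oracle", {
  set.seed(14)
  lens <- sample(200:800, 50, replace = TRUE)
  raw <- vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
  names(raw) <- sprintf("g%02d", 1:50)
  seqs <- tiny_seqs(utr3 = raw)
  site <- "ACTGCC"
  f <- set_frequency(gene_set(names(raw), "all"), seqs, "utr3", site)
  oracle <- sum(vapply(raw, naive_count, integer(1), site = site)) / (sum(lens) / 1000)
  expect_equal(as.numeric(f), oracle, tolerance = 1e-12)
})

test_that("Monte-Carlo p is 1 when the observed statistic sits at the null median", {
  # all genes share one sequence, so every random set has the same frequency
  raw <- setNames(rep(paste0("ACTGCC", strrep("G", 94)), 20), sprintf("g%02d", 1:20))
  seqs <- tiny_seqs(utr3 = raw)
  res <- mc_enrichment(gene_set(sprintf("g%02d", 1:5), "s"), names(raw),
                       seqs, "utr3", "ACTGCC", n_sims = 100, rng_seed = 1)
  expect_equal(res$p_empirical, 1)
  expect_equal(res$fold, 1)
})

test_that("the empirical p floors at 2/(n_sims+1) and engages tail extrapolation", {
  set.seed(15)
  # set genes stuffed with sites; background genes (sampled for the null) have none
  set_seqs <- setNames(rep(strrep("ACTGCC", 50), 10), sprintf("s%02d", 1:10))
  bg_seqs <- setNames(vapply(1:200, function(i)
    paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = ""),
    character(1)), sprintf("b%03d", 1:200))
  seqs <- tiny_seqs(utr3 = c(set_seqs, bg_seqs))
  res <- mc_enrichment(gene_set(names(set_seqs), "loaded"), names(bg_seqs),
                       seqs, "utr3", "ACTGCC", n_sims = 10000, rng_seed = 2)
  expect_equal(res$p_empirical, 2 / 10001)
  expect_false(is.na(res$p_tail))
  expect_lt(res$p_tail, 1e-10)
})

test_that("set larger than background and too-few simulations are rejected", {
  raw <- setNames(rep("ACGTACGTACGT", 5), sprintf("g%d", 1:5))
  seqs <- tiny_seqs(utr3 = raw)
  expect_error(mc_enrichment(gene_set(sprintf("g%d", 1:5), "s"),
                             sprintf("g%d", 1:3), seqs, "utr3", "ACTGCC",
                             n_sims = 100), "larger than the background")
  expect_error(mc_enrichment(gene_set("g1", "s"), sprintf("g%d", 1:5),
                             seqs, "utr3", "ACTGCC", n_sims = 10), "n_sims")
})

test_that("tail extrapolation reproduces closed-form Gaussian tails", {
  set.seed(16)
  null <- rnorm(50000)
  expect_equal(tail_extrapolate(mean(null), null), 1, tolerance = 1e-6)
  p6 <- tail_extrapolate(mean(null) + 6 * sd(null), null)
  expect_lt(abs(log(p6 / (2 * pnorm(-6)))), log(2))
  expect_warning(pna <- tail_extrapolate(1, rep(0.5, 100)), "degenerate")
  expect_true(is.na(pna))
})

test_that("the scan grid is reproducible under a fixed seed and has full dimensions", {
  cfg <- simulation_config(n_genes = 60, target_fraction = 0.25,
                           seed_density_target = 5, seed_density_background = 1,
                           utr_length_dist = list(utr5 = c(log(60), 0),
                                                  cds = c(log(60), 0),
                                                  utr3 = c(log(400), 0.2)),
                           rng_seed = 19)
  sim <- simulate_expression(cfg)
  sq <- simulate_sequences(cfg, sim$truth)
  tgt <- gene_set(sim$truth$gene_id[sim$truth$is_target], "targets")
  bg <- gene_set(sim$truth$gene_id, "all")
  g1 <- hexamer_scan_all(cfg$mirna, list(tgt), bg, sq$seqs,
                         regions = c("utr3", "cds"), n_sims = 100, rng_seed = 4)
  g2 <- hexamer_scan_all(cfg$mirna, list(tgt), bg, sq$seqs,
                         regions = c("utr3", "cds"), n_sims = 100, rng_seed = 4)
  expect_identical(g1, g2)
  expect_equal(nrow(g1), (nchar(cfg$mirna) - 5L) * 2L * 1L)
  # determinism of the single-cell routine too
  r1 <- mc_enrichment(tgt, bg, sq$seqs, "utr3", "ACTGCC", n_sims = 200, rng_seed = 6)
  r2 <- mc_enrichment(tgt, bg, sq$seqs, "utr3", "ACTGCC", n_sims = 200, rng_seed = 6)
  expect_identical(r1, r2)
})

test_that("planted seed density makes the seed window the most enriched window", {
  cfg <- simulation_config(n_genes = 300, target_fraction = 1 / 3,
                           seed_density_target = 5, seed_density_background = 1,
                           utr_length_dist = list(utr5 = c(log(60), 0),
                                                  cds = c(log(60), 0),
                                                  utr3 = c(log(1000), 0.3)),
                           rng_seed = 23)
  sim <- simulate_expression(cfg)
  sq <- simulate_sequences(cfg, sim$truth)
  tgt <- gene_set(sim$truth$gene_id[sim$truth$is_target], "targets")
  bg <- gene_set(sim$truth$gene_id, "all")
  grid <- hexamer_scan_all(cfg$mirna, list(tgt), bg, sq$seqs,
                           regions = "utr3", n_sims = 100, rng_seed = 7)
  expect_equal(grid$hexamer_start[which.max(grid$fold)], 2L)
  # targets carry 5 sites/kb vs 1/kb elsewhere; with targets inside the
  # background the expected seed-window fold is about 2
  expect_gt(grid$fold[grid$hexamer_start == 2L], 1.5)
})
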