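test_that("the enrichment ratio follows the four-arm formula", {
  pm <- arm_matrix(pd_test = 8, pd_control = 2, in_test = 1, in_control = 1)
  expect_equal(enrichment_ratio(pm)$mean_ratio, 4)

  pm2 <- arm_matrix(pd_test = 3, pd_control = 3, in_test = 3, in_control = 3)
  expect_equal(enrichment_ratio(pm2)$mean_ratio, 1)

  # knockdown in the input arm inflates the ratio through the denominator
  pm3 <- arm_matrix(pd_test = 4, pd_control = 2, in_test = 1, in_control = 2)
  expect_equal(enrichment_ratio(pm3)$mean_ratio, 4)
})

test_that("replicate ratios are averaged arithmetically before probe collapse", {
  design <- toy_design(2)
  v <- matrix(1, 1, 8, dimnames = list("p1", design$sample_id))
  pick <- function(arm, mirna, r)
    design$sample_id[design$arm == arm & design$mirna == mirna & design$replicate == r]
  v[, pick("pulldown", "test", 1)] <- 2   # replicate 1 ratio 2
  v[, pick("pulldown", "test", 2)] <- 4   # replicate 2 ratio 4
  pm <- probe_matrix(v, design, data.frame(probe_id = "p1", gene_id = "gA"))
  expect_equal(enrichment_ratio(pm)$mean_ratio, 3)
  expect_equal(enrichment_ratio(pm, average = "geometric")$mean_ratio,
               sqrt(8), tolerance = 1e-12)
})

test_that("the full enrichment stage equals a spreadsheet-style oracle on a 5-gene fixture", {
  f <- toy_fixture()
  tab <- enrichment_ratio(f$matrix)
  oracle <- oracle_ratio_table(f$values, f$design, f$gene_ids, "enrichment")
  expect_equal(setNames(tab$mean_ratio, tab$gene_id), oracle[sort(names(oracle))],
               tolerance = 1e-12)
  fc <- fold_change(f$matrix)
  oracle_fc <- oracle_ratio_table(f$values, f$design, f$gene_ids, "fold_change")
  expect_equal(setNames(fc$mean_fc, fc$gene_id), oracle_fc[sort(names(oracle_fc))],
               tolerance = 1e-12)
})

test_that("genes with nonpositive intensities are excluded with a logged count", {
  pm <- arm_matrix(pd_test = c(8, 8), pd_control = c(2, 0), in_test = c(1, 1),
                   in_control = c(1, 1), gene_ids = c("gA", "gB"))
  expect_message(tab <- enrichment_ratio(pm), "1 gene")
  expect_identical(tab$gene_id, "gA")
})

test_that("the log-normal background fit recovers closed-form parameters", {
  tab <- data.frame(gene_id = c("a", "b", "c"),
                    mean_ratio = 2^c(-1, 0, 1), log2_ratio = c(-1, 0, 1))
  thr <- fit_background(tab, n_sd = 1)
  expect_equal(thr$mu, 0)
  expect_equal(thr$sigma, 1)
  expect_equal(thr$fold_equivalent, 2)

  same <- data.frame(gene_id = c("a", "b"), mean_ratio = c(3, 3),
                     log2_ratio = log2(c(3, 3)))
  thr2 <- fit_background(same)
  expect_equal(thr2$sigma, 0)
  expect_equal(thr2$fold_equivalent, 3)

  expect_error(fit_background(tab[1, ]), "at least 2")
})

test_that("hit calling is boundary-inclusive and monotone in the SD multiplier", {
  tab <- data.frame(gene_id = c("a", "b", "c"),
                    mean_ratio = c(2.4, 2.5, 3.0),
                    log2_ratio = log2(c(2.4, 2.5, 3.0)))
  thr <- structure(list(mu = NA, sigma = NA, n_sd = 1, fold_equivalent = 2.5),
                   class = "HitThreshold")
  expect_setequal(call_hits(tab, thr)$members, c("b", "c"))

  set.seed(17)
  big <- data.frame(gene_id = sprintf("g%04d", 1:500),
                    mean_ratio = 2^rnorm(500), log2_ratio = NA)
  big$log2_ratio <- log2(big$mean_ratio)
  prev <- big$gene_id
  for (n_sd in c(0, 0.5, 1, 2, 4, 100)) {
    hits <- call_hits(big, fit_background(big, n_sd = n_sd))$members
    expect_true(all(hits %in% prev), label = sprintf("n_sd=%g nested", n_sd))
    prev <- hits
  }
  expect_length(prev, 0L)  # extreme multiplier empties the set
})

test_that("rescaling any single sample leaves hit calls invariant after refitting", {
  set.seed(33)
  v <- matrix(2^runif(8 * 4, 2, 10), 8, 4)
  pm1 <- arm_matrix(pd_test = v[, 1], pd_control = v[, 2],
                    in_test = v[, 3], in_control = v[, 4],
                    gene_ids = c("gA", "gA", "gB", "gC", "gC", "gD", "gE", "gE"))
  pm2 <- pm1
  pm2$values[, 2] <- pm2$values[, 2] * 3.7
  tab1 <- enrichment_ratio(pm1)
  tab2 <- enrichment_ratio(pm2)
  # every ratio changed by a common factor, so refitted hit calls agree
  expect_equal(sd(log2(tab2$mean_ratio) - log2(tab1$mean_ratio)), 0, tolerance = 1e-12)
  hits1 <- call_hits(tab1, fit_background(tab1))$members
  hits2 <- call_hits(tab2, fit_background(tab2))$members
  expect_setequal(hits1, hits2)
})

test_that("abundance-coupled capture applied to both pull-down arms cancels in the ratio", {
  f <- toy_fixture()
  tab1 <- enrichment_ratio(f$matrix)
  v <- f$values
  pd_cols <- f$design$sample_id[f$design$arm == "pulldown"]
  abundance_factor <- 2^seq(0.1, 0.8, length.out = nrow(v))  # per-probe
  v[, pd_cols] <- v[, pd_cols] * abundance_factor
  pm2 <- probe_matrix(v, f$design,
                      data.frame(probe_id = f$probe_ids, gene_id = f$gene_ids))
  expect_equal(enrichment_ratio(pm2)$mean_ratio, tab1$mean_ratio, tolerance = 1e-12)
})

test_that("the fitted background SD on null simulations matches the lognormal-mean propagation oracle", {
  cfg <- simulation_config(n_genes = 10000, probes_per_gene = 1,
                           target_fraction = 0, noise_sd = 0.5,
                           n_replicates = 2, rng_seed = 29)
  sim <- simulate_expression(cfg)
  tab <- enrichment_ratio(sim$matrix)
  thr <- fit_background(tab)
  expect_lt(abs(thr$sigma - fw_sigma_log2(0.5, 2)) / fw_sigma_log2(0.5, 2), 0.05)
})

test_that("gene-set intersection and the overlap report behave set-theoretically", {
  a <- gene_set(c("A", "B", "C"), "a")
  b <- gene_set(c("B", "C", "D"), "b")
  expect_setequal(overlap(a, b)$members, c("B", "C"))
  expect_length(overlap(gene_set(c("A"), "x"), gene_set(c("B"), "y")), 0L)
  rep <- overlap_report(a, b)
  expect_equal(c(rep$a_only, rep$b_only, rep$both), c(1L, 1L, 2L))
  expect_error(gene_set(c("A", "Z"), "bad", universe = c("A", "B")), "outside")
})

test_that("enrichment stratification produces nested sets of the right sizes", {
  tab <- data.frame(gene_id = c("a", "b", "c"), mean_ratio = c(1.5, 3, 5),
                    log2_ratio = log2(c(1.5, 3, 5)))
  sets <- stratify_by_enrichment(tab, c(1, 2, 4))
  expect_equal(lengths(lapply(sets, `[[`, "members")), c(3L, 2L, 1L))
  expect_true(all(sets[[3]]$members %in% sets[[2]]$members))
  expect_true(all(sets[[2]]$members %in% sets[[1]]$members))
  expect_error(stratify_by_enrichment(tab, c(4, 1)), "ascending")
})
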