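test_that("the hypergeometric upper tail matches closed forms and enumeration", {
  expect_equal(hypergeom_p(0, 5, 5, 10), 1)
  expect_equal(hypergeom_p(5, 5, 5, 10), 1 / choose(10, 5), tolerance = 1e-12)
  expect_error(hypergeom_p(6, 5, 5, 10), "margins")
  expect_error(hypergeom_p(2, 11, 5, 10), "margins")

  # spot-check exhaustive subset enumeration at small N (full sweep to N=12
  # runs in the acceptance suite)
  for (N in c(5, 8)) for (K in 0:N) for (n in 0:N) for (k in 0:min(K, n))
    expect_equal(hypergeom_p(k, K, n, N), enum_hyper_tail(k, K, n, N),
                 tolerance = 1e-10,
                 label = sprintf("k=%d K=%d n=%d N=%d", k, K, n, N))
})

test_that("the tail is monotone in k, symmetric in (K, n), and the pmf sums to 1", {
  N <- 40; K <- 12; n <- 15
  p <- hypergeom_p(0:min(K, n), K, n, N)
  expect_true(all(diff(p) < 0))
  expect_equal(hypergeom_p(5, K, n, N), hypergeom_p(5, n, K, N), tolerance = 1e-12)
  # P(X = k) from tail differences sums to 1
  ks <- 0:min(K, n)
  pmf <- hypergeom_p(ks, K, n, N) - c(hypergeom_p(ks[-1], K, n, N), 0)
  expect_equal(sum(pmf), 1, tolerance = 1e-10)
})

test_that("pathway over-representation matches hand-computed hypergeometric p-values", {
  universe <- sprintf("g%02d", 1:20)
  pw <- pathway_collection(list(P1 = universe[1:5], P2 = universe[6:15],
                                P3 = universe[16:20]), universe)
  query <- gene_set(universe[c(1:4, 6, 16)], "q")
  res <- enrich_pathways(query, pw, p_cut = 0.05)
  byid <- setNames(res$p, res$pathway_id)
  expect_equal(byid[["P1"]], hypergeom_p(4, 5, 6, 20), tolerance = 1e-12)
  expect_equal(byid[["P2"]], hypergeom_p(1, 10, 6, 20), tolerance = 1e-12)
  expect_equal(byid[["P3"]], hypergeom_p(1, 5, 6, 20), tolerance = 1e-12)
  expect_identical(res$pathway_id[1], "P1")

  # query genes outside the universe are dropped with a warning
  expect_warning(res2 <- enrich_pathways(gene_set(c(universe[1:3], "gZZ"), "q2"),
                                         pw), "dropped")
  expect_equal(unique(res2$n), 3L)
  expect_error(suppressWarnings(enrich_pathways(gene_set("gZZ", "q3"), pw)),
               "empty")
})

test_that("a query equal to one pathway gives that pathway the minimal p", {
  universe <- sprintf("g%02d", 1:30)
  pw <- pathway_collection(list(A = universe[1:6], B = universe[7:20],
                                C = universe[21:30]), universe)
  res <- enrich_pathways(gene_set(universe[1:6], "exactlyA"), pw)
  expect_identical(res$pathway_id[1], "A")
  expect_equal(res$p[1], hypergeom_p(6, 6, 6, 30), tolerance = 1e-12)
})

test_that("random queries produce significant pathways at about the nominal rate", {
  set.seed(51)
  universe <- sprintf("g%04d", 1:500)
  pw <- pathway_collection(setNames(lapply(1:200, function(i)
    sample(universe, sample(20:50, 1))), sprintf("P%03d", 1:200)), universe)
  nsig <- replicate(30, {
    q <- gene_set(sample(universe, 100), "q")
    sum(enrich_pathways(q, pw, p_cut = 0.05)$significant)
  })
  # hypergeometric p is discrete and conservative: at most the nominal rate
  expect_lt(mean(nsig), 0.05 * 200 * 1.2)
  expect_gt(mean(nsig), 0.5)
})

test_that("the pathway-overlap network counts query-restricted shared genes", {
  universe <- sprintf("g%02d", 1:30)
  pw <- pathway_collection(list(A = universe[1:10], B = universe[6:15],
                                C = universe[20:25], D = universe[1:10]),
                           universe)
  query <- gene_set(universe[c(1:8, 20:22)], "q")
  res <- enrich_pathways(query, pw, p_cut = 1)
  net <- build_network(res, query, pw, p_cut = 1)
  edge_of <- function(a, b) {
    e <- net$edges
    e$shared[(e$from == a & e$to == b) | (e$from == b & e$to == a)]
  }
  # A and D are identical pathways: edge weight = their shared query overlap
  expect_equal(edge_of("A", "D"), 8L)
  # A and B share g06..g10 but only g06..g08 are in the query
  expect_equal(edge_of("A", "B"), 3L)
  # C shares nothing with A/B -> no edge
  expect_length(edge_of("A", "C"), 0L)
  expect_length(edge_of("B", "C"), 0L)
  # full-membership option
  net2 <- build_network(res, query, pw, p_cut = 1, edge_genes = "all")
  e2 <- net2$edges
  expect_equal(e2$shared[(e2$from == "A" & e2$to == "B")], 5L)
})

test_that("two disjoint significant pathways give two nodes and no edges", {
  universe <- sprintf("g%02d", 1:40)
  pw <- pathway_collection(list(A = universe[1:10], B = universe[11:20]), universe)
  query <- gene_set(universe[c(1:9, 11:19)], "q")
  res <- enrich_pathways(query, pw, p_cut = 0.01)
  expect_true(all(res$significant))
  net <- build_network(res, query, pw, p_cut = 0.01)
  expect_equal(nrow(net$nodes), 2L)
  expect_equal(nrow(net$edges), 0L)
})

test_that("non-significant pathways can be retained flagged for gray rendering", {
  universe <- sprintf("g%02d", 1:40)
  pw <- pathway_collection(list(A = universe[1:10], B = universe[11:20]), universe)
  query <- gene_set(universe[1:9], "q")
  res <- enrich_pathways(query, pw, p_cut = 1e-6)
  net <- build_network(res, query, pw, p_cut = 1e-6, keep_nonsignificant = TRUE)
  expect_equal(nrow(net$nodes), 2L)
  expect_true(any(!net$nodes$significant))
})

test_that("GMT round-trips and agrees with an independent reader", {
  path <- file.path(tempdir(), "toy.gmt")
  sets <- list(P1 = c("a", "b", "c"), P2 = c("b", "d"), P3 = c("e", "f", "g", "h"))
  write_gmt(sets, path)
  pc <- read_gmt(path)
  expect_equal(pc$pathways, sets)
  ext <- fgsea::gmtPathways(path)
  expect_equal(ext[names(sets)], sets)

  # SIF export is source<TAB>shared<TAB>target
  universe <- unique(unlist(sets))
  pw <- pathway_collection(sets, universe)
  res <- enrich_pathways(gene_set(c("a", "b", "c", "d"), "q"), pw, p_cut = 1)
  net <- build_network(res, gene_set(c("a", "b", "c", "d"), "q"), pw, p_cut = 1)
  sif <- file.path(tempdir(), "net.sif"); nodes <- file.path(tempdir(), "nodes.tsv")
  write_network(net, sif, nodes)
  lines <- readLines(sif)
  expect_true(all(vapply(strsplit(lines, "\t"), length, integer(1)) == 3L))
  unlink(c(path, sif, nodes))
})
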