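#' Hypergeometric upper-tail probability of gene-set overlap
#'
#' P(X >= k) for X ~ Hypergeometric with `K` pathway genes, `n` query genes
#' drawn from a universe of `N`. Inclusive tail (over-representation at least
#' as extreme as observed), computed via `stats::phyper`, which works in log
#' space internally and is stable for extreme tails. Vectorized over `k`,
#' `K`, `n`.
#'
#' @param k overlap count(s).
#' @param K pathway size(s) in the universe.
#' @param n query size(s) in the universe.
#' @param N universe size.
#' @return upper-tail probability in (0, 1].
#' @export
hypergeom_p <- function(k, K, n, N) {
  if (any(K > N) || any(n > N))
    stopf("inconsistent margins: K and n must not exceed N")
  if (any(k < 0) || any(k > pmin(K, n)))
    stopf("inconsistent margins: k must satisfy 0 <= k <= min(K, n)")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Pathway over-representation of a query gene set
#'
#' For every pathway in the collection, tests whether the query overlaps it
#' more than expected under random sampling from the universe, with the
#' hypergeometric upper tail. Query genes outside the universe are dropped
#' with a warning. No multiple-testing correction gates the `significant`
#' flag (the raw-p threshold, default 0.001, does); a Benjamini-Hochberg
#' column is emitted for information.
#'
#' @param query a [gene_set()] or character vector of gene ids.
#' @param pathways a [pathway_collection()].
#' @param p_cut raw-p significance threshold (default 0.001).
#' @return a `PathwayResult` data.frame: `pathway_id`, `description`, `k`,
#'   `K`, `n`, `N`, `p`, `p_bh`, `significant`, sorted by `p`.
#' @export
enrich_pathways <- function(query, pathways, p_cut = 0.001) {
  stopifnot(inherits(pathways, "PathwayCollection"))
  check_scalar(p_cut, "pathway_p_cut", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = FALSE)
  q <- if (inherits(query, "GeneSet")) query$members else unique(as.character(query))
  dropped <- setdiff(q, pathways$universe)
  if (length(dropped))
    warnf("%d query gene(s) outside the pathway universe were dropped", length(dropped))
  q <- intersect(q, pathways$universe)
  if (!length(q)) stopf("query is empty after intersection with the universe")
  N <- length(pathways$universe)
  n <- length(q)
  K <- lengths(pathways$pathways)
  k <- vapply(pathways$pathways, function(p) length(intersect(p, q)), integer(1))
  p <- hypergeom_p(k, K, n, N)
  out <- data.frame(pathway_id = names(pathways$pathways),
                    description = unname(pathways$descriptions[names(pathways$pathways)]),
                    k = unname(k), K = unname(K), n = n, N = N,
                    p = unname(p), p_bh = p.adjust(unname(p), "BH"),
                    significant = unname(p) < p_cut,
                    row.names = NULL)
  out <- out[order(out$p, out$pathway_id), ]
  rownames(out) <- NULL
  class(out) <- c("PathwayResult", "data.frame")
  out
}

#' Pathway-overlap network of enriched pathways
#'
#' Nodes are the pathways passing the significance cut (optionally all
#' pathways, with the non-significant ones flagged so viewers can gray them
#' out). Node size is the number of query genes in the pathway (`k`). An edge
#' connects two pathways sharing at least one gene; by default the shared
#' count is taken over the query-restricted overlaps (the genes driving the
#' enrichment), with full pathway membership available behind a flag.
#'
#' @param results a `PathwayResult` from [enrich_pathways()].
#' @param query the same query passed to [enrich_pathways()].
#' @param pathways the same [pathway_collection()].
#' @param p_cut significance threshold for node retention (default 0.001).
#' @param keep_nonsignificant if `TRUE`, non-significant pathways stay in the
#'   network flagged `significant = FALSE`.
#' @param edge_genes `"query"` (default) counts shared genes among the
#'   query-restricted pathway overlaps; `"all"` among full pathway members.
#' @return object of class `PathwayNetwork`: list of data.frames `nodes`
#'   (`pathway_id`, `k`, `p`, `significant`) and `edges` (`from`, `to`,
#'   `shared`), with zero-shared edges omitted.
#' @export
build_network <- function(results, query, pathways, p_cut = 0.001,
                          keep_nonsignificant = FALSE,
                          edge_genes = c("query", "all")) {
  edge_genes <- match.arg(edge_genes)
  stopifnot(inherits(results, "PathwayResult"), inherits(pathways, "PathwayCollection"))
  q <- if (inherits(query, "GeneSet")) query$members else as.character(query)
  q <- intersect(q, pathways$universe)
  keep <- if (keep_nonsignificant) rep(TRUE, nrow(results)) else results$p < p_cut
  nodes <- data.frame(pathway_id = results$pathway_id[keep],
                      k = results$k[keep], p = results$p[keep],
                      significant = results$p[keep] < p_cut,
                      row.names = NULL)
  members <- lapply(pathways$pathways[nodes$pathway_id], function(g) {
    if (edge_genes == "query") intersect(g, q) else g
  })
  edges <- list()
  ids <- nodes$pathway_id
  if (length(ids) >= 2L) {
    for (i in seq_len(length(ids) - 1L)) for (j in seq(i + 1L, length(ids))) {
      sh <- length(intersect(members[[ids[i]]], members[[ids[j]]]))
      if (sh >= 1L)
        edges[[length(edges) + 1L]] <- data.frame(from = ids[i], to = ids[j],
                                                  shared = sh)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(0), to = character(0), shared = integer(0))
  structure(list(nodes = nodes, edges = edges), class = "PathwayNetwork")
}

#' @export
print.PathwayNetwork <- function(x, ...) {
  cat(sprintf("PathwayNetwork: %d nodes, %d edges\n", nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Export a pathway network as a SIF-style edge list plus node attributes
#'
#' The SIF file has lines `source<TAB>shared_count<TAB>target`; the node
#' attribute TSV has columns `pathway_id`, `k`, `p`, `significant` —
#' consumable by standard graph viewers.
#'
#' @param network a [build_network()] result.
#' @param sif_path output path for the edge list.
#' @param nodes_path output path for the node attributes.
#' @export
write_network <- function(network, sif_path, nodes_path) {
  stopifnot(inherits(network, "PathwayNetwork"))
  lines <- sprintf("%s\t%d\t%s", network$edges$from, network$edges$shared,
                   network$edges$to)
  writeLines(lines, sif_path)
  write_tsv(network$nodes, nodes_path)
  invisible(sif_path)
}
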