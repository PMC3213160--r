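#' Create a labelled gene set
#'
#' @param members character vector of gene ids (de-duplicated, order kept).
#' @param label short label used in reports.
#' @param universe optional character vector of gene ids the set lives in;
#'   when given, members must be a subset.
#' @return object of class `GeneSet`.
#' @export
gene_set <- function(members, label = "set", universe = NULL) {
  members <- unique(as.character(members))
  if (!is.null(universe)) {
    universe <- unique(as.character(universe))
    out <- setdiff(members, universe)
    if (length(out))
      stopf("gene set '%s' has %d member(s) outside its universe (e.g. '%s')",
            label, length(out), out[1L])
  }
  structure(list(label = label, members = members, universe = universe),
            class = "GeneSet")
}

#' @export
print.GeneSet <- function(x, ...) {
  cat(sprintf("GeneSet '%s': %d genes%s\n", x$label, length(x$members),
              if (is.null(x$universe)) "" else
                sprintf(" (universe %d)", length(x$universe))))
  invisible(x)
}

#' @export
length.GeneSet <- function(x) length(x$members)

#' Intersect two gene sets
#'
#' Used e.g. to overlap the hit sets called independently in two cell lines.
#' The result carries the provenance of both parents in its label and keeps
#' the union of any universes.
#'
#' @param set_a,set_b [gene_set()] objects.
#' @return a `GeneSet` whose members are the intersection.
#' @export
overlap <- function(set_a, set_b) {
  stopifnot(inherits(set_a, "GeneSet"), inherits(set_b, "GeneSet"))
  uni <- if (is.null(set_a$universe) && is.null(set_b$universe)) NULL
         else union(set_a$universe %||% character(0), set_b$universe %||% character(0))
  gene_set(intersect(set_a$members, set_b$members),
           label = paste(set_a$label, set_b$label, sep = " & "),
           universe = uni)
}

#' Two-set overlap report
#'
#' @param set_a,set_b [gene_set()] objects.
#' @return data.frame with one row: labels and counts `a_only`, `b_only`,
#'   `both`.
#' @export
overlap_report <- function(set_a, set_b) {
  both <- intersect(set_a$members, set_b$members)
  data.frame(set_a = set_a$label, set_b = set_b$label,
             a_only = length(setdiff(set_a$members, both)),
             b_only = length(setdiff(set_b$members, both)),
             both = length(both))
}

#' Read / write one-gene-per-line lists
#'
#' Plain text, one gene id per line; blank lines and `#` comments ignored.
#' Externally predicted target lists (e.g. TargetScan exports) are consumed
#' this way.
#'
#' @param path file path.
#' @param label label for the resulting set (default: file name).
#' @return `read_gene_list`: a [gene_set()]; `write_gene_list`: the path,
#'   invisibly.
#' @export
read_gene_list <- function(path, label = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("\r$", "", lines))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  gene_set(lines, label = label %||% basename(path))
}

#' @rdname read_gene_list
#' @param set a [gene_set()].
#' @export
write_gene_list <- function(set, path) {
  writeLines(set$members, path)
  invisible(path)
}

#' Construct a pathway collection
#'
#' @param pathways named list of character vectors (pathway id -> member gene
#'   ids).
#' @param universe character vector of gene ids forming the testing universe
#'   (typically all expressed genes on the platform). Members are intersected
#'   with the universe before testing; pathways empty after intersection are
#'   dropped.
#' @param descriptions optional named character vector of pathway descriptions.
#' @return object of class `PathwayCollection`.
#' @export
pathway_collection <- function(pathways, universe, descriptions = NULL) {
  stopifnot(is.list(pathways), !is.null(names(pathways)))
  universe <- unique(as.character(universe))
  pathways <- lapply(pathways, function(g) intersect(unique(as.character(g)), universe))
  keep <- lengths(pathways) > 0L
  pathways <- pathways[keep]
  desc <- descriptions[names(pathways)] %||% setNames(rep("", length(pathways)), names(pathways))
  desc[is.na(desc)] <- ""
  structure(list(pathways = pathways, universe = universe, descriptions = desc),
            class = "PathwayCollection")
}

#' @export
print.PathwayCollection <- function(x, ...) {
  cat(sprintf("PathwayCollection: %d pathways over a universe of %d genes (sizes %d-%d)\n",
              length(x$pathways), length(x$universe),
              if (length(x$pathways)) min(lengths(x$pathways)) else 0L,
              if (length(x$pathways)) max(lengths(x$pathways)) else 0L))
  invisible(x)
}

#' Read / write gene sets in GMT format
#'
#' GMT is tab-separated: set id, description, then member gene ids.
#'
#' @param path file path.
#' @param universe testing universe passed to [pathway_collection()]; if
#'   `NULL`, the union of all member genes is used.
#' @return `read_gmt`: a [pathway_collection()]; `write_gmt`: the path,
#'   invisibly.
#' @export
read_gmt <- function(path, universe = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stopf("%s: line %d has fewer than 3 tab-separated fields", path, short[1L])
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) stopf("%s: duplicate pathway id '%s'", path, ids[duplicated(ids)][1L])
  desc <- setNames(vapply(fields, `[[`, character(1), 2L), ids)
  sets <- setNames(lapply(fields, function(f) f[-(1:2)]), ids)
  pathway_collection(sets, universe %||% unique(unlist(sets)), desc)
}

#' @rdname read_gmt
#' @param collection a [pathway_collection()] (or plain named list of gene id
#'   vectors).
#' @export
write_gmt <- function(collection, path) {
  if (inherits(collection, "PathwayCollection")) {
    sets <- collection$pathways
    desc <- collection$descriptions
  } else {
    sets <- collection
    desc <- setNames(rep("", length(sets)), names(sets))
  }
  lines <- vapply(names(sets), function(id) {
    paste(c(id, desc[[id]] %||% "", sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
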