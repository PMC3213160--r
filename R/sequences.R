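REGIONS <- c("utr5", "cds", "utr3")

#' Construct a region-annotated sequence set
#'
#' One record per gene and region (5'UTR, CDS, 3'UTR), stored as DNA in mRNA
#' sense orientation.
#'
#' @param utr5,cds,utr3 `Biostrings::DNAStringSet` (or character vectors)
#'   named by gene id. Genes may be missing from individual regions.
#' @param provenance optional data.frame `gene_id`, `transcript_id` recording
#'   which transcript was retained per gene.
#' @return object of class `RegionSequenceSet`: list with one `DNAStringSet`
#'   per region plus `provenance`.
#' @export
region_sequence_set <- function(utr5 = NULL, cds = NULL, utr3 = NULL,
                                provenance = NULL) {
  as_set <- function(x) {
    if (is.null(x)) return(Biostrings::DNAStringSet())
    x <- if (is(x, "DNAStringSet")) x else DNAStringSet(toupper(x))
    if (length(x) && is.null(names(x))) stopf("region sequences must be named by gene id")
    if (anyDuplicated(names(x)))
      stopf("more than one sequence for gene '%s' in a region; transcript selection must happen first",
            names(x)[duplicated(names(x))][1L])
    x
  }
  structure(list(utr5 = as_set(utr5), cds = as_set(cds), utr3 = as_set(utr3),
                 provenance = provenance),
            class = "RegionSequenceSet")
}

#' @export
print.RegionSequenceSet <- function(x, ...) {
  cat(sprintf("RegionSequenceSet: %d genes with 3'UTR, %d with CDS, %d with 5'UTR\n",
              length(x$utr3), length(x$cds), length(x$utr5)))
  invisible(x)
}

#' Read region-annotated transcript sequences from FASTA
#'
#' Headers are `>geneID|region` or `>geneID|transcriptID|region` with region
#' one of `utr5`, `cds`, `utr3`. When several transcripts map to the same
#' gene, the transcript with the longest 3'UTR is retained (all of its
#' regions); ties are broken lexicographically by transcript id. Transcripts
#' with no 3'UTR record count as length 0.
#'
#' @param path FASTA file path.
#' @return a [region_sequence_set()] with per-gene provenance.
#' @export
read_region_fasta <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  seqs <- readDNAStringSet(path)
  if (!length(seqs)) stopf("%s: no FASTA records", path)
  parts <- strsplit(sub(" .*$", "", names(seqs)), "|", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2L | nf > 3L))
    stopf("%s: header '%s' is not geneID|region or geneID|transcriptID|region",
          path, names(seqs)[which(nf < 2L | nf > 3L)[1L]])
  gene <- vapply(parts, `[[`, character(1), 1L)
  tx <- ifelse(nf == 3L, vapply(parts, function(p) p[[2L]], character(1)), gene)
  region <- vapply(parts, function(p) p[[length(p)]], character(1))
  bad <- which(!region %in% REGIONS)
  if (length(bad))
    stopf("%s: unknown region '%s' in header '%s'", path, region[bad[1L]],
          names(seqs)[bad[1L]])

  # longest-3'UTR transcript selection, ties lexicographic by transcript id
  key <- paste(gene, tx)
  u3len <- setNames(rep(0L, length(unique(key))), unique(key))
  is3 <- region == "utr3"
  u3len[key[is3]] <- Biostrings::width(seqs)[is3]
  tx_tab <- unique(data.frame(key = key, gene = gene, tx = tx, stringsAsFactors = FALSE))
  tx_tab$u3 <- u3len[tx_tab$key]
  tx_tab <- tx_tab[order(tx_tab$gene, -tx_tab$u3, tx_tab$tx), ]
  chosen <- tx_tab[!duplicated(tx_tab$gene), ]
  keep <- key %in% chosen$key

  out <- list()
  for (r in REGIONS) {
    sel <- keep & region == r
    s <- seqs[sel]
    names(s) <- gene[sel]
    if (anyDuplicated(names(s)))
      stopf("%s: gene '%s' has duplicate '%s' records for one transcript",
            path, names(s)[duplicated(names(s))][1L], r)
    out[[r]] <- s
  }
  region_sequence_set(out$utr5, out$cds, out$utr3,
                      provenance = data.frame(gene_id = chosen$gene,
                                              transcript_id = chosen$tx,
                                              row.names = NULL))
}

#' Write a region sequence set as FASTA with `>geneID|region` headers
#'
#' Records are written in deterministic order (region by region, genes in
#' stored order) so identical inputs give byte-identical files.
#'
#' @param seqs a [region_sequence_set()].
#' @param path output FASTA path.
#' @export
write_region_fasta <- function(seqs, path) {
  stopifnot(inherits(seqs, "RegionSequenceSet"))
  all <- DNAStringSet()
  for (r in REGIONS) {
    s <- seqs[[r]]
    if (!length(s)) next
    names(s) <- paste(names(s), r, sep = "|")
    all <- c(all, s)
  }
  writeXStringSet(all, path, width = 70L)
  invisible(path)
}
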