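#' Build a per-chromosome gene interval index
#'
#' Wraps the gene model in per-chromosome [IRanges::IRanges] objects so that
#' nearest-gene queries run in logarithmic time per query. Query answers are
#' independent of the input order of the intervals.
#'
#' @param genes Gene model data.frame from [read_gene_model()] (columns
#'   `name`, `chrom`, `start` 0-based inclusive, `end` exclusive).
#' @return An object of class `gene_index`.
#' @export
build_gene_index <- function(genes) {
  stopifnot(is.data.frame(genes))
  if (nrow(genes) && any(genes$start >= genes$end)) {
    stop("gene intervals must satisfy start < end", call. = FALSE)
  }
  by_chrom <- split(genes, genes$chrom)
  index <- lapply(by_chrom, function(g) {
    # BED [start, end) -> 1-based closed [start + 1, end]
    ir <- IRanges::IRanges(start = g$start + 1L, end = g$end)
    names(ir) <- g$name
    ir
  })
  structure(list(chroms = index, n_genes = nrow(genes)), class = "gene_index")
}

#' @export
print.gene_index <- function(x, ...) {
  cat(sprintf("<gene_index> %d gene(s) on %d chromosome(s)\n",
              x$n_genes, length(x$chroms)))
  invisible(x)
}

#' Annotate variants with their nearest gene
#'
#' A variant lying inside a gene (1-based position within the gene's
#' half-open BED interval) gets distance 0; otherwise the distance is the
#' number of bases from the variant to the closer gene boundary, so a variant
#' immediately adjacent to a gene has distance 1. Ties — several genes
#' containing the variant, or several equidistant genes — are broken by the
#' lexicographically smallest gene name, which keeps the annotation
#' deterministic. Strand is never consulted. A variant on a chromosome with
#' no genes gets `NA` for both gene and distance.
#'
#' @param variants Data.frame with columns `rsid`, `chrom`, `pos` (1-based).
#' @param index A `gene_index` from [build_gene_index()].
#' @return Data.frame with columns `rsid`, `gene`, `distance`, one row per
#'   input variant, in input order.
#' @export
annotate_nearest_gene <- function(variants, index) {
  stopifnot(inherits(index, "gene_index"), is.data.frame(variants))
  n <- nrow(variants)
  gene <- rep(NA_character_, n)
  distance <- rep(NA_real_, n)
  if (!n) {
    return(data.frame(rsid = character(), gene = character(),
                      distance = numeric(), stringsAsFactors = FALSE))
  }
  for (chrom in unique(variants$chrom)) {
    if (is.na(chrom) || is.null(index$chroms[[chrom]])) next
    genes_ir <- index$chroms[[chrom]]
    rows <- which(variants$chrom == chrom & !is.na(variants$pos))
    if (!length(rows)) next
    pos <- variants$pos[rows]
    q <- IRanges::IRanges(start = pos, width = 1L)
    hits <- IRanges::distanceToNearest(q, genes_ir, select = "all")
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    # distance on our convention: 0 inside, else gap + 1 (adjacency = 1 base)
    g_start <- IRanges::start(genes_ir)[sh]
    g_end <- IRanges::end(genes_ir)[sh]
    v_pos <- pos[qh]
    d <- pmax(0, g_start - v_pos, v_pos - g_end)
    g_name <- names(genes_ir)[sh]
    # per query: minimal distance, then lexicographically smallest name
    ord <- order(qh, d, g_name)
    first <- !duplicated(qh[ord])
    sel <- ord[first]
    gene[rows[qh[sel]]] <- g_name[sel]
    distance[rows[qh[sel]]] <- d[sel]
  }
  data.frame(rsid = variants$rsid, gene = gene, distance = distance,
             stringsAsFactors = FALSE)
}

#' Annotate the variant universe of a score collection
#'
#' Convenience wrapper: collects the unique variants (rsid, chrom, pos)
#' across a list of scores and annotates each with its nearest gene. When
#' the same rsid appears with several coordinates, the first encountered
#' coordinate wins.
#'
#' @param files List of [score_file()] objects.
#' @param index A `gene_index`.
#' @return Data.frame `rsid`, `gene`, `distance`, one row per unique rsid.
#' @export
annotate_score_files <- function(files, index) {
  tabs <- lapply(files, function(f) f$variants[, c("rsid", "chrom", "pos")])
  all_v <- do.call(rbind, tabs)
  all_v <- all_v[!duplicated(all_v$rsid), , drop = FALSE]
  annotate_nearest_gene(all_v, index)
}
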