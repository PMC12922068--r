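# Locus-gene genomic association: intragenic overlap and 50-kb flanking
# neighbourhoods, with strand relations carried as attributes.

locus_gene_links <- function(loci, genes, q_idx, s_idx, relation, distance) {
  out <- data.frame(
    locus_id = loci$feature_id[q_idx],
    gene_id = genes$feature_id[s_idx],
    relation = rep_len(relation, length(q_idx)),
    distance_bp = rep_len(as.integer(distance), length(q_idx)),
    locus_strand = loci$strand[q_idx],
    gene_strand = genes$strand[s_idx],
    same_strand = loci$strand[q_idx] == genes$strand[s_idx],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$locus_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find host genes of retroelement loci
#'
#' Links every locus to every gene it overlaps by at least one base on the
#' same chromosome, regardless of strand (a locus inside a protein-coding
#' gene on one strand and a lncRNA on the other yields two links). Strand
#' agreement is recorded, never used for detection.
#'
#' @param loci,genes Feature tables ([genomic_features()]) sharing one
#'   coordinate convention and chromosome naming style.
#' @return A link `data.frame`: `locus_id`, `gene_id`,
#'   `relation = "intragenic"`, `distance_bp = 0`, both strands and
#'   `same_strand`, ordered by (locus, gene).
#' @export
find_host_genes <- function(loci, genes) {
  check_chrom_compat(loci$chrom, genes$chrom)
  hits <- GenomicRanges::findOverlaps(features_to_granges(loci),
                                      features_to_granges(genes),
                                      ignore.strand = TRUE)
  locus_gene_links(loci, genes,
                   S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits),
                   relation = "intragenic", distance = 0L)
}

#' Find genes within a flanking window of retroelement loci
#'
#' Links every non-overlapping same-chromosome (locus, gene) pair whose
#' end-to-start gap is at most `window` base pairs. The distance is the
#' number of bases strictly between the two inclusive intervals (adjacent
#' intervals have distance 0); overlapping pairs are reported only by
#' [find_host_genes()].
#'
#' @param loci,genes Feature tables.
#' @param window Flank size in bp on each side, default 50000.
#' @return A link `data.frame` with `relation = "nearby"` and the gap in
#'   `distance_bp`.
#' @export
find_nearby_genes <- function(loci, genes, window = 50000L) {
  stopifnot(window > 0)
  check_chrom_compat(loci$chrom, genes$chrom)
  lg <- features_to_granges(loci)
  gg <- features_to_granges(genes)
  hits <- GenomicRanges::findOverlaps(lg, gg, maxgap = as.integer(window),
                                      ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  overlap <- loci$start[q] <= genes$end[s] & genes$start[s] <= loci$end[q]
  gap <- pmax(genes$start[s] - loci$end[q], loci$start[q] - genes$end[s]) - 1L
  keep <- !overlap & gap <= window
  locus_gene_links(loci, genes, q[keep], s[keep],
                   relation = "nearby", distance = gap[keep])
}

#' Join differential-expression results onto locus-gene links
#'
#' Adds the locus's and gene's log2 fold change and adjusted p-value to each
#' link. With `only_de = TRUE` only links whose gene passes the DE threshold
#' (`padj < alpha` and `|log2fc| >= lfc_min`) are kept; otherwise links with
#' missing DE records are retained with blank fields.
#'
#' @param links Link table from [find_host_genes()] or
#'   [find_nearby_genes()].
#' @param locus_de,gene_de DE tables keyed by feature id (may be `NULL`).
#' @param only_de Keep only links with a differentially expressed gene.
#' @param alpha,lfc_min DE thresholds used when `only_de` is set.
#' @return The link table with `locus_log2fc`, `locus_padj`, `gene_log2fc`,
#'   `gene_padj` columns appended.
#' @export
annotate_links <- function(links, locus_de = NULL, gene_de = NULL,
                           only_de = FALSE, alpha = 0.05, lfc_min = 1) {
  pull <- function(de, ids, col) {
    if (is.null(de)) rep(NA_real_, length(ids)) else de[[col]][match(ids, de$feature_id)]
  }
  links$locus_log2fc <- pull(locus_de, links$locus_id, "log2fc")
  links$locus_padj <- pull(locus_de, links$locus_id, "padj")
  links$gene_log2fc <- pull(gene_de, links$gene_id, "log2fc")
  links$gene_padj <- pull(gene_de, links$gene_id, "padj")
  if (only_de) {
    keep <- !is.na(links$gene_padj) & links$gene_padj < alpha &
      !is.na(links$gene_log2fc) & abs(links$gene_log2fc) >= lfc_min
    links <- links[keep, , drop = FALSE]
    rownames(links) <- NULL
  }
  links
}
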