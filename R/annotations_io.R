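#' @import methods
#' @importFrom stats coef cor cor.test lm median model.matrix p.adjust pnorm
#'   qnorm rbinom rnorm runif sd setNames var
#' @importFrom utils read.csv read.delim write.csv write.table
"_PACKAGE"

# Internal coordinate convention: 1-based, fully closed (Ensembl GTF style).
# BED input/output is converted at the package boundary.

FEATURE_COLUMNS <- c("feature_id", "kind", "chrom", "start", "end",
                     "strand", "biotype", "tss")

#' Construct a genomic feature table
#'
#' Builds the package's standard feature table (one row per gene or
#' retroelement locus) in 1-based inclusive coordinates, validating the
#' coordinate and strand invariants.
#'
#' @param feature_id Character vector of unique feature identifiers.
#' @param kind `"gene"` or `"locus"`, recycled as needed.
#' @param chrom Chromosome names.
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param strand `"+"` or `"-"`.
#' @param biotype Optional biotype labels (`protein_coding`, `lncRNA`, ...).
#' @param tss Optional transcription start positions. For genes, defaults to
#'   `start` on the plus strand and `end` on the minus strand.
#'
#' @return A `data.frame` with columns `feature_id`, `kind`, `chrom`,
#'   `start`, `end`, `strand`, `biotype`, `tss`.
#' @export
genomic_features <- function(feature_id, kind, chrom, start, end, strand,
                             biotype = NA_character_, tss = NA_integer_) {
  n <- length(feature_id)
  df <- data.frame(
    feature_id = as.character(feature_id),
    kind = rep_len(as.character(kind), n),
    chrom = rep_len(as.character(chrom), n),
    start = as.integer(start),
    end = as.integer(end),
    strand = rep_len(as.character(strand), n),
    biotype = rep_len(as.character(biotype), n),
    tss = rep_len(as.integer(tss), n),
    stringsAsFactors = FALSE
  )
  fill <- df$kind == "gene" & is.na(df$tss)
  df$tss[fill] <- ifelse(df$strand[fill] == "+", df$start[fill], df$end[fill])
  validate_features(df)
}

#' Validate a feature table
#'
#' Checks the feature-table invariants: positive, ordered coordinates,
#' `+`/`-` strand, unique ids, and the strand-aware TSS rule for genes.
#'
#' @param features A feature table as returned by [genomic_features()].
#' @return The validated table, invisibly unchanged.
#' @export
validate_features <- function(features) {
  stopifnot(is.data.frame(features))
  missing_cols <- setdiff(FEATURE_COLUMNS, names(features))
  if (length(missing_cols)) {
    stop("feature table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(features$feature_id)) {
    stop("duplicate feature_id in annotation set: ",
         paste(unique(features$feature_id[duplicated(features$feature_id)]),
               collapse = ", "))
  }
  if (any(features$start < 1L)) stop("feature start must be >= 1")
  if (any(features$end < features$start)) {
    stop("feature end < start for: ",
         paste(features$feature_id[features$end < features$start],
               collapse = ", "))
  }
  if (!all(features$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  has_tss <- features$kind == "gene" & !is.na(features$tss)
  expect_tss <- ifelse(features$strand[has_tss] == "+",
                       features$start[has_tss], features$end[has_tss])
  if (any(features$tss[has_tss] != expect_tss)) {
    stop("gene tss must equal start (+) or end (-)")
  }
  features
}

#' Convert a feature table to GRanges
#'
#' @param features A feature table ([genomic_features()]).
#' @return A [GenomicRanges::GRanges] with `feature_id`, `kind` and `biotype`
#'   metadata columns.
#' @export
features_to_granges <- function(features) {
  validate_features(features)
  GenomicRanges::GRanges(
    seqnames = features$chrom,
    ranges = IRanges::IRanges(start = features$start, end = features$end),
    strand = features$strand,
    feature_id = features$feature_id,
    kind = features$kind,
    biotype = features$biotype
  )
}

#' Read gene annotation from a GTF file
#'
#' Imports annotation records (via \pkg{rtracklayer}) and returns the
#' package's feature table. Coordinates stay 1-based inclusive; the TSS is
#' derived strand-aware (`start` on `+`, `end` on `-`). Records without a
#' definite `+`/`-` strand are rejected with a warning; the count of rejected
#' records is available as `attr(x, "n_rejected")`.
#'
#' @param path Path to a GTF file.
#' @param feature_kinds GTF record types to keep (column 3), default `"gene"`.
#' @return A feature table with an additional `name` column (gene_name
#'   attribute where present).
#' @export
read_gtf <- function(path, feature_kinds = "gene") {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readLines(path)
  body <- which(!startsWith(raw, "#") & nzchar(raw))
  if (length(body)) {
    nfield <- lengths(strsplit(raw[body], "\t", fixed = TRUE))
    bad <- body[nfield < 9L]
    if (length(bad)) {
      stop(sprintf("GTF parse error at line %d: expected 9 tab-separated fields, found %d",
                   bad[1L], nfield[match(bad[1L], body)]))
    }
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[as.character(gr$type) %in% feature_kinds]
  strand_chr <- as.character(BiocGenerics::strand(gr))
  keep <- strand_chr %in% c("+", "-")
  n_rejected <- sum(!keep)
  if (n_rejected > 0L) {
    warning(sprintf("%d record(s) with unknown strand rejected", n_rejected))
  }
  gr <- gr[keep]
  ids <- if (!is.null(gr$gene_id)) gr$gene_id else as.character(seq_along(gr))
  biotype <- if (!is.null(gr$gene_biotype)) gr$gene_biotype else NA_character_
  feats <- genomic_features(
    feature_id = ids,
    kind = "gene",
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    biotype = biotype
  )
  feats$name <- if (!is.null(gr$gene_name)) gr$gene_name else NA_character_
  attr(feats, "n_rejected") <- n_rejected
  feats
}

#' Write a feature table as GTF
#'
#' @param features A feature table; `kind == "gene"` rows are written as
#'   `gene` records, `kind == "locus"` rows keep their kind as record type.
#' @param path Output path.
#' @param source Value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_features_gtf <- function(features, path, source = "retromethyl") {
  validate_features(features)
  attrs <- sprintf('gene_id "%s";', features$feature_id)
  has_name <- "name" %in% names(features) & !is.na(features[["name"]])
  if (any(has_name)) {
    attrs[has_name] <- paste(attrs[has_name],
                             sprintf('gene_name "%s";', features$name[has_name]))
  }
  has_bt <- !is.na(features$biotype)
  attrs[has_bt] <- paste(attrs[has_bt],
                         sprintf('gene_biotype "%s";', features$biotype[has_bt]))
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
                   features$chrom, source,
                   ifelse(features$kind == "locus", "locus", "gene"),
                   features$start, features$end, features$strand, attrs)
  writeLines(lines, path)
  invisible(path)
}

#' Read retroelement locus coordinates from BED
#'
#' Accepts BED3+ (0-based half-open) and converts to the internal 1-based
#' inclusive convention. Records without a strand column are assigned `"+"`
#' with a warning and flagged via the `strand_imputed` column, because the
#' downstream strand dichotomy needs a value.
#'
#' @param path Path to a BED file; the name column carries the locus id.
#' @return A feature table with `kind == "locus"` and a logical
#'   `strand_imputed` column.
#' @export
read_locus_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "bed")
  zero <- BiocGenerics::width(gr) < 1L
  if (any(zero)) {
    bad <- if (!is.null(gr$name)) gr$name[zero] else which(zero)
    stop("zero-length BED interval(s) rejected: ", paste(bad, collapse = ", "))
  }
  strand_chr <- as.character(BiocGenerics::strand(gr))
  imputed <- !strand_chr %in% c("+", "-")
  if (any(imputed)) {
    warning(sprintf("%d unstranded BED record(s): strand recorded as '+'",
                    sum(imputed)))
    strand_chr[imputed] <- "+"
  }
  ids <- if (!is.null(gr$name)) gr$name else paste0("locus_", seq_along(gr))
  feats <- genomic_features(
    feature_id = ids,
    kind = "locus",
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = strand_chr
  )
  feats$strand_imputed <- imputed
  feats
}

#' Write a feature table as BED6
#'
#' Converts from the internal 1-based inclusive convention to BED's 0-based
#' half-open coordinates.
#'
#' @param features A feature table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features_bed <- function(features, path) {
  validate_features(features)
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   features$chrom, features$start - 1L, features$end,
                   features$feature_id, features$strand)
  writeLines(lines, path)
  invisible(path)
}

# Candidate header names for differential-expression/methylation tables.
# There is no fixed upstream schema, so common DESeq2-style exports are the
# defaults and alternatives can be passed explicitly.
de_column_candidates <- function() {
  list(feature_id = c("feature_id", "gene_id", "locus_id", "id"),
       log2fc = c("log2FoldChange", "log2fc", "logFC"),
       pvalue = c("pvalue", "p_value", "PValue"),
       padj = c("padj", "FDR", "adj_pvalue"))
}

match_columns <- function(found, candidates) {
  res <- vapply(candidates, function(cands) {
    hit <- cands[cands %in% found]
    if (length(hit)) hit[1L] else NA_character_
  }, character(1))
  missing <- names(res)[is.na(res)]
  if (length(missing)) {
    stop("missing mandatory column(s) ", paste(missing, collapse = ", "),
         "; columns found: ", paste(found, collapse = ", "))
  }
  res
}

num_or_na <- function(x) suppressWarnings(as.numeric(x))

check_prob <- function(p, what) {
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) stop(what, " outside [0, 1] in rows: ",
                     paste(which(bad), collapse = ", "))
  p
}

#' Read a per-tool differential-expression table
#'
#' Tab-separated with a header; `NA`/empty p-values are kept as missing and
#' treated as non-significant downstream, never imputed.
#'
#' @param path Path to the TSV.
#' @param tool Tool label attached to every row (e.g. `"toolA"`).
#' @param subtype Subtype label attached to every row (e.g. `"CMS1"`).
#' @param columns Named list of candidate column names per field; see
#'   `de_column_candidates` defaults (DESeq2-style `log2FoldChange`,
#'   `pvalue`, `padj`).
#' @return A `data.frame` with columns `feature_id`, `log2fc`, `pvalue`,
#'   `padj`, `tool`, `subtype`, one row per input row.
#' @export
read_de_table <- function(path, tool = "generic", subtype = NA_character_,
                          columns = de_column_candidates()) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character")
  cols <- match_columns(names(tab), columns)
  data.frame(
    feature_id = tab[[cols[["feature_id"]]]],
    log2fc = num_or_na(tab[[cols[["log2fc"]]]]),
    pvalue = check_prob(num_or_na(tab[[cols[["pvalue"]]]]), "pvalue"),
    padj = check_prob(num_or_na(tab[[cols[["padj"]]]]), "padj"),
    tool = tool,
    subtype = subtype,
    stringsAsFactors = FALSE
  )
}

#' Read a differential-methylation table and join the CpG manifest
#'
#' The manifest maps each probe to its position and TSS200 promoter
#' membership (semicolon-separated gene ids). Sites absent from the manifest
#' are retained (with empty promoter membership) only if the methylation
#' table itself carries `chrom`/`position`; otherwise they are dropped and
#' counted in `attr(x, "n_dropped")`.
#'
#' @param path Differential-methylation TSV with at least `cpg_id` and
#'   the DE-style columns (`log2FoldChange`, `pvalue`, `padj`); optional
#'   `chrom`, `position`, `beta_tumor`, `beta_normal`.
#' @param manifest_path Manifest TSV with `cpg_id`, `chrom`, `position`,
#'   optional `strand`, and `tss200` (semicolon-separated gene ids; may be
#'   empty).
#' @return A `data.frame` of CpG sites with columns `cpg_id`, `chrom`,
#'   `position`, `strand`, `meth_log2fc`, `pvalue`, `padj`, optional betas,
#'   and a list column `promoter_of`.
#' @export
read_methylation_table <- function(path, manifest_path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (!file.exists(manifest_path)) stop("no such file: ", manifest_path)
  meth <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                     colClasses = "character")
  man <- read.delim(manifest_path, header = TRUE, sep = "\t",
                    check.names = FALSE, colClasses = "character")
  if (!"cpg_id" %in% names(meth)) stop("methylation table lacks cpg_id column")
  need_man <- setdiff(c("cpg_id", "chrom", "position"), names(man))
  if (length(need_man)) {
    stop("manifest lacks column(s): ", paste(need_man, collapse = ", "))
  }
  if (anyDuplicated(man$cpg_id)) {
    stop("duplicate cpg_id in manifest: ",
         paste(unique(man$cpg_id[duplicated(man$cpg_id)]), collapse = ", "))
  }
  cols <- match_columns(names(meth), de_column_candidates()[c("log2fc", "pvalue", "padj")])
  idx <- match(meth$cpg_id, man$cpg_id)
  in_man <- !is.na(idx)

  chrom <- rep(NA_character_, nrow(meth))
  position <- rep(NA_integer_, nrow(meth))
  strand <- rep(NA_character_, nrow(meth))
  chrom[in_man] <- man$chrom[idx[in_man]]
  position[in_man] <- as.integer(man$position[idx[in_man]])
  if ("strand" %in% names(man)) strand[in_man] <- man$strand[idx[in_man]]
  if ("chrom" %in% names(meth)) {
    chrom[!in_man] <- meth$chrom[!in_man]
  }
  if ("position" %in% names(meth)) {
    position[!in_man] <- as.integer(meth$position[!in_man])
  }

  tss200 <- rep("", nrow(meth))
  if ("tss200" %in% names(man)) tss200[in_man] <- man$tss200[idx[in_man]]
  tss200[is.na(tss200)] <- ""
  promoter_of <- strsplit(tss200, ";", fixed = TRUE)
  promoter_of <- lapply(promoter_of, function(x) x[nzchar(x)])

  sites <- data.frame(
    cpg_id = meth$cpg_id,
    chrom = chrom,
    position = position,
    strand = ifelse(is.na(strand) | !strand %in% c("+", "-"), "+", strand),
    strand_known = !is.na(strand) & strand %in% c("+", "-"),
    meth_log2fc = num_or_na(meth[[cols[["log2fc"]]]]),
    pvalue = check_prob(num_or_na(meth[[cols[["pvalue"]]]]), "pvalue"),
    padj = check_prob(num_or_na(meth[[cols[["padj"]]]]), "padj"),
    stringsAsFactors = FALSE
  )
  for (b in c("beta_tumor", "beta_normal")) {
    if (b %in% names(meth)) {
      v <- num_or_na(meth[[b]])
      bad <- !is.na(v) & (v < 0 | v > 1)
      if (any(bad)) {
        stop("beta-value outside [0, 1] for site(s): ",
             paste(meth$cpg_id[bad], collapse = ", "))
      }
      sites[[b]] <- v
    }
  }
  sites$promoter_of <- promoter_of

  keep <- !is.na(sites$chrom) & !is.na(sites$position)
  n_dropped <- sum(!keep)
  sites <- sites[keep, , drop = FALSE]
  rownames(sites) <- NULL
  attr(sites, "n_dropped") <- n_dropped
  sites
}

# Detect 'chr1' vs '1' naming clashes before an interval join.
check_chrom_compat <- function(a_chrom, b_chrom) {
  ca <- unique(a_chrom)
  cb <- unique(b_chrom)
  if (length(ca) && length(cb) && !length(intersect(ca, cb))) {
    pa <- any(grepl("^chr", ca))
    pb <- any(grepl("^chr", cb))
    if (pa != pb) {
      stop("mixed chromosome naming styles ('chr1' vs '1'); ",
           "rename seqnames to a common style before joining")
    }
  }
  invisible(NULL)
}

#' Write a result table as TSV
#'
#' Fixed column order, tab-separated, no quoting or row names; used for all
#' pipeline exports so reruns are byte-identical.
#'
#' @param x A data frame (list columns are collapsed with `";"`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  x <- as.data.frame(x)
  for (col in names(x)) {
    if (is.list(x[[col]])) {
      x[[col]] <- vapply(x[[col]], paste, character(1), collapse = ";")
    }
  }
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
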