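# CpG methylation / expression coupling: promoter beta aggregation,
# windowed CpG-partner pairing, effect-size filtering, Spearman
# correlation, and the strand/promoter interaction regressions.

#' Filtering thresholds for CpG-partner pairs
#'
#' Thresholds follow the published filtering rules: CpG sites must show
#' differential methylation beyond `|log2FC| > 0.1`, partners (genes or
#' loci) beyond `|log2FC| > 1`, each with significance below 0.05. All
#' fold-change inequalities are strict; the significance column is the
#' adjusted p-value by default and can be toggled to the raw p-value.
#'
#' @param meth_lfc_min Minimum absolute methylation log2FC (strict),
#'   default 0.1.
#' @param meth_alpha Methylation significance threshold, default 0.05.
#' @param expr_lfc_min Minimum absolute expression log2FC (strict),
#'   default 1.
#' @param expr_alpha Expression significance threshold, default 0.05.
#' @param use_adjusted_meth_p,use_adjusted_expr_p Use adjusted p-values
#'   (default) or raw p-values for the two significance checks.
#' @return A `filter_config` list.
#' @export
filter_config <- function(meth_lfc_min = 0.1, meth_alpha = 0.05,
                          expr_lfc_min = 1, expr_alpha = 0.05,
                          use_adjusted_meth_p = TRUE,
                          use_adjusted_expr_p = TRUE) {
  stopifnot(meth_lfc_min > 0, expr_lfc_min > 0,
            meth_alpha > 0, meth_alpha < 1, expr_alpha > 0, expr_alpha < 1)
  structure(list(meth_lfc_min = meth_lfc_min, meth_alpha = meth_alpha,
                 expr_lfc_min = expr_lfc_min, expr_alpha = expr_alpha,
                 use_adjusted_meth_p = use_adjusted_meth_p,
                 use_adjusted_expr_p = use_adjusted_expr_p),
            class = "filter_config")
}

#' Aggregate promoter methylation per gene
#'
#' Arithmetic mean of beta-values over each gene's TSS200 promoter sites
#' (from the manifest's promoter membership). Genes with no promoter sites
#' are absent from the result.
#'
#' @param sites CpG site table from [read_methylation_table()] carrying a
#'   beta column and the `promoter_of` list column.
#' @param beta_col Name of the beta column to average, default
#'   `"beta_tumor"`.
#' @return A `data.frame` with `gene_id`, `mean_beta`, `n_sites`.
#' @export
aggregate_promoter_beta <- function(sites, beta_col = "beta_tumor") {
  if (!beta_col %in% names(sites)) stop("no such beta column: ", beta_col)
  beta <- sites[[beta_col]]
  bad <- !is.na(beta) & (beta < 0 | beta > 1)
  if (any(bad)) {
    stop("beta-value outside [0, 1] for site(s): ",
         paste(sites$cpg_id[bad], collapse = ", "))
  }
  n_per_site <- lengths(sites$promoter_of)
  gene <- unlist(sites$promoter_of)
  if (!length(gene)) {
    return(data.frame(gene_id = character(0), mean_beta = numeric(0),
                      n_sites = integer(0)))
  }
  b <- rep(beta, n_per_site)
  keep <- !is.na(b)
  agg <- tapply(b[keep], gene[keep], mean)
  out <- data.frame(gene_id = names(agg), mean_beta = as.numeric(agg),
                    n_sites = as.integer(table(gene[keep])[names(agg)]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Shared pairing engine: site position within [start - window, end + window]
# of the partner; distance is the offset beyond the partner boundary
# (0 when the site lies inside the partner interval).
pair_sites_features <- function(sites, partners, window, kind) {
  stopifnot(window > 0)
  check_chrom_compat(sites$chrom, partners$chrom)
  site_gr <- GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$position, end = sites$position)
  )
  part_gr <- features_to_granges(partners)
  hits <- GenomicRanges::findOverlaps(site_gr, part_gr,
                                      maxgap = as.integer(window),
                                      ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  dist <- pmax(0L, partners$start[s] - sites$position[q],
               sites$position[q] - partners$end[s])
  keep <- dist <= window
  q <- q[keep]
  s <- s[keep]
  cpg_strand <- if ("strand" %in% names(sites)) sites$strand[q] else rep("+", length(q))
  strand_known <- if ("strand_known" %in% names(sites)) sites$strand_known[q] else rep(FALSE, length(q))
  out <- data.frame(
    pair_kind = kind,
    cpg_id = sites$cpg_id[q],
    partner_id = partners$feature_id[s],
    X1 = sites$meth_log2fc[q],
    X2 = as.integer(cpg_strand == partners$strand[s]),
    distance_bp = as.integer(dist[keep]),
    meth_pvalue = sites$pvalue[q],
    meth_padj = sites$padj[q],
    strand_low_confidence = !strand_known,
    stringsAsFactors = FALSE
  )
  if (kind == "cpg_gene") {
    out$X3 <- as.integer(mapply(function(i, g) g %in% sites$promoter_of[[i]],
                                q, partners$feature_id[s]))
  }
  out <- out[order(out$cpg_id, out$partner_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pair CpG sites with genes
#'
#' One pair for every (site, gene) with the site position within
#' `window` bp of the gene boundaries (i.e. inside
#' `[start - window, end + window]`). The promoter indicator `X3` comes
#' from the manifest's TSS200 membership, not from geometry; the strand
#' indicator `X2` compares the probe strand (manifest strand where present,
#' otherwise `"+"` with a low-confidence flag) to the gene strand.
#'
#' @param sites CpG table from [read_methylation_table()].
#' @param genes Gene feature table.
#' @param window Pairing window in bp, default 3000.
#' @return An unfiltered pair `data.frame` with `pair_kind = "cpg_gene"`,
#'   design columns `X1` (methylation log2FC), `X2`, `X3`, the pairing
#'   distance and the site's significance columns.
#' @export
pair_cpg_gene <- function(sites, genes, window = 3000L) {
  pair_sites_features(sites, genes, window, "cpg_gene")
}

#' Pair CpG sites with retroelement loci
#'
#' As [pair_cpg_gene()] with a wider default window and no promoter
#' indicator.
#'
#' @param sites CpG table.
#' @param loci Locus feature table.
#' @param window Pairing window in bp, default 10000.
#' @return An unfiltered pair `data.frame` with `pair_kind = "cpg_locus"`.
#' @export
pair_cpg_locus <- function(sites, loci, window = 10000L) {
  pair_sites_features(sites, loci, window, "cpg_locus")
}

#' Filter CpG-partner pairs on effect size and significance
#'
#' Joins the partner's differential expression (`Y`, the partner log2FC)
#' onto each pair and keeps pairs where `|X1| > meth_lfc_min` with
#' methylation significance below `meth_alpha` AND `|Y| > expr_lfc_min`
#' with expression significance below `expr_alpha` (all fold-change bounds
#' strict). When a consensus locus set is supplied, the partner must belong
#' to it. Pairs whose partner lacks a DE record are dropped and counted in
#' `attr(x, "n_no_de")`; missing values never pass a threshold. Filtering
#' is idempotent.
#'
#' @param pairs Pair table from [pair_cpg_gene()] / [pair_cpg_locus()].
#' @param partner_de DE table for the partners (genes or loci).
#' @param cfg A [filter_config()].
#' @param consensus Optional character vector of consensus partner ids.
#' @return The surviving pairs with `Y`, `expr_pvalue`, `expr_padj` columns.
#' @export
filter_pairs <- function(pairs, partner_de, cfg = filter_config(),
                         consensus = NULL) {
  stopifnot(inherits(cfg, "filter_config"))
  idx <- match(pairs$partner_id, partner_de$feature_id)
  pairs$Y <- partner_de$log2fc[idx]
  pairs$expr_pvalue <- partner_de$pvalue[idx]
  pairs$expr_padj <- partner_de$padj[idx]
  n_no_de <- sum(is.na(idx))
  meth_p <- if (cfg$use_adjusted_meth_p) pairs$meth_padj else pairs$meth_pvalue
  expr_p <- if (cfg$use_adjusted_expr_p) pairs$expr_padj else pairs$expr_pvalue
  keep <- !is.na(pairs$X1) & abs(pairs$X1) > cfg$meth_lfc_min &
    !is.na(meth_p) & meth_p < cfg$meth_alpha &
    !is.na(pairs$Y) & abs(pairs$Y) > cfg$expr_lfc_min &
    !is.na(expr_p) & expr_p < cfg$expr_alpha
  if (!is.null(consensus)) keep <- keep & pairs$partner_id %in% consensus
  keep[is.na(keep)] <- FALSE
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_no_de") <- n_no_de
  out
}

#' Spearman correlation between differential methylation and expression
#'
#' Rank correlation of `X1` (CpG methylation log2FC) against `Y` (partner
#' expression log2FC) over filtered pairs, with midrank tie handling and a
#' two-sided p-value (exact for n <= 10 without ties, t-approximation
#' otherwise). Pair and uniqueness counts are reported alongside, since a
#' CpG may pair with several partners and vice versa.
#'
#' @param pairs Filtered pair table carrying `X1` and `Y`.
#' @return A list: `rho`, `pvalue`, `n_pairs`, `n_unique_cpgs`,
#'   `n_unique_partners`, and a `defined` flag (`FALSE` when either
#'   variable is constant).
#' @export
spearman_coupling <- function(pairs) {
  n <- nrow(pairs)
  if (n < 3L) stop("need at least 3 pairs for a correlation test")
  counts <- list(n_pairs = n,
                 n_unique_cpgs = length(unique(pairs$cpg_id)),
                 n_unique_partners = length(unique(pairs$partner_id)))
  if (sd(pairs$X1) == 0 || sd(pairs$Y) == 0) {
    return(c(list(rho = NA_real_, pvalue = NA_real_, defined = FALSE), counts))
  }
  ct <- suppressWarnings(
    cor.test(pairs$X1, pairs$Y, method = "spearman", exact = n <= 10L)
  )
  c(list(rho = unname(ct$estimate), pvalue = ct$p.value, defined = TRUE),
    counts)
}

regression_result <- function(model, applicable, reason = NA_character_,
                              coefficients = NULL, n_pairs = 0L,
                              residual_sd = NA_real_, extra = list()) {
  structure(c(list(model = model, applicable = applicable,
                   inapplicability_reason = reason,
                   coefficients = coefficients, n_pairs = n_pairs,
                   residual_sd = residual_sd), extra),
            class = "regression_result")
}

coef_table <- function(fit, betas) {
  s <- summary(fit)$coefficients
  data.frame(beta = betas, term = rownames(s),
             estimate = s[, "Estimate"], se = s[, "Std. Error"],
             t = s[, "t value"], pvalue = s[, "Pr(>|t|)"],
             row.names = NULL, stringsAsFactors = FALSE)
}

check_design <- function(d, col_labels) {
  consts <- names(col_labels)[vapply(names(col_labels), function(nm) sd(d[[nm]]) == 0, logical(1))]
  if (length(consts)) {
    return(sprintf("constant %s", paste(col_labels[consts], collapse = " and ")))
  }
  NULL
}

#' Interaction regression for CpG-locus pairs
#'
#' Ordinary least squares of the locus expression log2FC on the CpG
#' methylation log2FC, the same-strand indicator and their interaction:
#' `Y = b0 + b1*X1 + b2*X2 + b3*X1*X2 + e`, `e ~ N(0, sigma)`.
#' If any design column (X1, X2 or the interaction) has zero variance, or
#' the design is rank-deficient, the model is reported as not applicable
#' with the reason (e.g. when every pair lies on the same strand).
#'
#' @param pairs Filtered `cpg_locus` pair table with `Y`, `X1`, `X2`.
#' @return A `regression_result` list: `model = "eq_locus"`, `applicable`,
#'   `inapplicability_reason`, a coefficient table (`beta0`..`beta3` with
#'   estimate, SE, t, p), `n_pairs`, `residual_sd`.
#' @export
fit_locus_model <- function(pairs) {
  n <- nrow(pairs)
  if (n < 5L) {
    return(regression_result("eq_locus", FALSE,
                             sprintf("only %d pairs (minimum 5)", n), n_pairs = n))
  }
  d <- data.frame(Y = pairs$Y, X1 = pairs$X1, X2 = pairs$X2)
  d$X1X2 <- d$X1 * d$X2
  reason <- check_design(d[c("X1", "X2", "X1X2")],
                         c(X1 = "methylation log2FC (X1)",
                           X2 = "strand indicator (X2)",
                           X1X2 = "strand interaction (X1:X2)"))
  if (!is.null(reason)) {
    return(regression_result("eq_locus", FALSE, reason, n_pairs = n))
  }
  X <- model.matrix(~ X1 * X2, d)
  if (qr(X)$rank < ncol(X)) {
    return(regression_result("eq_locus", FALSE, "rank-deficient design",
                             n_pairs = n))
  }
  fit <- lm(Y ~ X1 * X2, data = d)
  regression_result("eq_locus", TRUE,
                    coefficients = coef_table(fit, paste0("beta", 0:3)),
                    n_pairs = n, residual_sd = summary(fit)$sigma)
}

#' Interaction regression for CpG-gene pairs
#'
#' OLS of the gene expression log2FC on the methylation log2FC with strand
#' and promoter indicators and both interactions:
#' `Y = b0 + b1*X1 + b2*X2 + b3*X3 + b4*X1*X2 + b5*X1*X3 + e`.
#' The same applicability guards apply per design column (a data set in
#' which no CpG lies in a promoter, or all pairs share a strand, is not
#' fittable). When applicable, the result also reports whether the promoter
#' interaction flips the sign of the methylation slope (`sign(b1)` vs
#' `sign(b1 + b5)`).
#'
#' @param pairs Filtered `cpg_gene` pair table with `Y`, `X1`, `X2`, `X3`.
#' @return A `regression_result` list with `beta0`..`beta5` and a
#'   `promoter_sign_flip` flag.
#' @export
fit_gene_model <- function(pairs) {
  n <- nrow(pairs)
  if (n < 7L) {
    return(regression_result("eq_gene", FALSE,
                             sprintf("only %d pairs (minimum 7)", n), n_pairs = n))
  }
  d <- data.frame(Y = pairs$Y, X1 = pairs$X1, X2 = pairs$X2, X3 = pairs$X3)
  d$X1X2 <- d$X1 * d$X2
  d$X1X3 <- d$X1 * d$X3
  reason <- check_design(d[c("X1", "X2", "X3", "X1X2", "X1X3")],
                         c(X1 = "methylation log2FC (X1)",
                           X2 = "strand indicator (X2)",
                           X3 = "promoter indicator (X3)",
                           X1X2 = "strand interaction (X1:X2)",
                           X1X3 = "promoter interaction (X1:X3)"))
  if (!is.null(reason)) {
    return(regression_result("eq_gene", FALSE, reason, n_pairs = n))
  }
  X <- model.matrix(~ X1 + X2 + X3 + X1:X2 + X1:X3, d)
  if (qr(X)$rank < ncol(X)) {
    return(regression_result("eq_gene", FALSE, "rank-deficient design",
                             n_pairs = n))
  }
  fit <- lm(Y ~ X1 + X2 + X3 + X1:X2 + X1:X3, data = d)
  cf <- coef_table(fit, paste0("beta", 0:5))
  b1 <- cf$estimate[cf$beta == "beta1"]
  b5 <- cf$estimate[cf$beta == "beta5"]
  regression_result("eq_gene", TRUE, coefficients = cf, n_pairs = n,
                    residual_sd = summary(fit)$sigma,
                    extra = list(promoter_sign_flip = b1 != 0 &&
                                   sign(b1) != sign(b1 + b5)))
}
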