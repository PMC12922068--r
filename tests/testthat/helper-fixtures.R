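# In-code fixtures and independent oracles shared across test files.

# Random feature table on one chromosome (used by interval-join oracles).
random_features <- function(n, kind, chrom = "chr1", max_pos = 1e6,
                            max_len = 5000) {
  start <- sample.int(max_pos, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  genomic_features(
    feature_id = sprintf("%s%04d", toupper(substr(kind, 1, 1)), seq_len(n)),
    kind = kind, chrom = chrom, start = start, end = start + len - 1L,
    strand = sample(c("+", "-"), n, replace = TRUE)
  )
}

random_sites <- function(n, chrom = "chr1", max_pos = 1e6) {
  data.frame(
    cpg_id = sprintf("cg%05d", seq_len(n)),
    chrom = chrom,
    position = sample.int(max_pos, n, replace = TRUE),
    strand = "+", strand_known = TRUE,
    meth_log2fc = stats::rnorm(n, 0, 0.5),
    pvalue = stats::runif(n), padj = stats::runif(n),
    promoter_of = I(replicate(n, character(0), simplify = FALSE)),
    stringsAsFactors = FALSE
  )
}

random_de <- function(ids, seed_lfc = NULL) {
  n <- length(ids)
  data.frame(feature_id = ids,
             log2fc = if (is.null(seed_lfc)) stats::rnorm(n, 0, 1.5) else seed_lfc,
             pvalue = stats::runif(n), padj = stats::runif(n),
             tool = "generic", subtype = NA_character_,
             stringsAsFactors = FALSE)
}

# Naive double-loop Cohen's kappa on two category vectors (the oracle is
# a direct transcription of the observed/chance agreement definitions).
naive_kappa <- function(a, b) {
  n <- length(a)
  levs <- c("up", "down", "ns")
  p0 <- sum(a == b) / n
  pe <- 0
  for (lev in levs) {
    pe <- pe + (sum(a == lev) / n) * (sum(b == lev) / n)
  }
  list(kappa = (p0 - pe) / (1 - pe), p0 = p0, pe = pe)
}

# Brute-force all-pairs interval relations under 1-based inclusive
# coordinates: overlap, and gap (bases strictly between the intervals).
brute_force_links <- function(loci, genes, window = NULL) {
  rows <- list()
  for (i in seq_len(nrow(loci))) {
    for (j in seq_len(nrow(genes))) {
      if (loci$chrom[i] != genes$chrom[j]) next
      overlap <- loci$start[i] <= genes$end[j] && genes$start[j] <= loci$end[i]
      if (is.null(window)) {
        if (overlap) {
          rows[[length(rows) + 1L]] <- data.frame(
            locus_id = loci$feature_id[i], gene_id = genes$feature_id[j],
            distance_bp = 0L, stringsAsFactors = FALSE)
        }
      } else if (!overlap) {
        gap <- max(genes$start[j] - loci$end[i], loci$start[i] - genes$end[j]) - 1L
        if (gap <= window) {
          rows[[length(rows) + 1L]] <- data.frame(
            locus_id = loci$feature_id[i], gene_id = genes$feature_id[j],
            distance_bp = gap, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(locus_id = character(0), gene_id = character(0),
                      distance_bp = integer(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$locus_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Brute-force CpG-feature pairing: site position within
# [start - window, end + window].
brute_force_pairs <- function(sites, feats, window) {
  rows <- list()
  for (i in seq_len(nrow(sites))) {
    for (j in seq_len(nrow(feats))) {
      if (sites$chrom[i] != feats$chrom[j]) next
      d <- max(0L, feats$start[j] - sites$position[i],
               sites$position[i] - feats$end[j])
      if (d <= window) {
        rows[[length(rows) + 1L]] <- data.frame(
          cpg_id = sites$cpg_id[i], partner_id = feats$feature_id[j],
          distance_bp = d, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(cpg_id = character(0), partner_id = character(0),
                      distance_bp = integer(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$cpg_id, out$partner_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Vectorized all-pairs scan over the full (locus, gene) index grid;
# returns host (overlap) and nearby (gap <= window) link sets at once.
all_pairs_scan <- function(loci, genes, window) {
  idx <- expand.grid(i = seq_len(nrow(loci)), j = seq_len(nrow(genes)))
  same <- loci$chrom[idx$i] == genes$chrom[idx$j]
  ov <- loci$start[idx$i] <= genes$end[idx$j] &
    genes$start[idx$j] <= loci$end[idx$i]
  gap <- pmax(genes$start[idx$j] - loci$end[idx$i],
              loci$start[idx$i] - genes$end[idx$j]) - 1L
  mk <- function(keep, dist) {
    out <- data.frame(locus_id = loci$feature_id[idx$i[keep]],
                      gene_id = genes$feature_id[idx$j[keep]],
                      distance_bp = as.integer(dist),
                      stringsAsFactors = FALSE)
    out <- out[order(out$locus_id, out$gene_id), , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  list(host = mk(same & ov, 0L),
       nearby = mk(same & !ov & gap <= window, gap[same & !ov & gap <= window]))
}

# Vectorized all-pairs scan for CpG-feature pairing (boundary-offset rule).
all_pairs_site_scan <- function(sites, feats, window) {
  idx <- expand.grid(i = seq_len(nrow(sites)), j = seq_len(nrow(feats)))
  same <- sites$chrom[idx$i] == feats$chrom[idx$j]
  d <- pmax(0L, feats$start[idx$j] - sites$position[idx$i],
            sites$position[idx$i] - feats$end[idx$j])
  keep <- same & d <= window
  out <- data.frame(cpg_id = sites$cpg_id[idx$i[keep]],
                    partner_id = feats$feature_id[idx$j[keep]],
                    distance_bp = as.integer(d[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$cpg_id, out$partner_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Row-by-row reimplementation of both consensus policies.
brute_force_consensus <- function(tables, policy) {
  ids <- sort(unique(unlist(lapply(tables, `[[`, "feature_id"))))
  keep <- character(0)
  for (id in ids) {
    sig <- logical(0); big <- logical(0); full <- logical(0); lfc <- numeric(0)
    for (tool in names(tables)) {
      t <- tables[[tool]]
      k <- match(id, t$feature_id)
      s <- !is.na(k) && !is.na(t$padj[k]) && t$padj[k] < policy$alpha
      b <- !is.na(k) && !is.na(t$log2fc[k]) && abs(t$log2fc[k]) >= policy$lfc_min
      sig[tool] <- s; big[tool] <- b; full[tool] <- s && b
      lfc[tool] <- if (is.na(k)) NA_real_ else t$log2fc[k]
    }
    sel <- if (policy$mode == "all_significant_two_lfc") {
      all(sig) && sum(big) >= 2
    } else {
      full[policy$anchor_tool] &&
        any(full[setdiff(names(tables), policy$anchor_tool)])
    }
    if (!sel) next
    signs <- unique(sign(lfc[sig & !is.na(lfc)]))
    signs <- signs[signs != 0]
    if (length(signs) == 1) keep <- c(keep, id)
  }
  keep
}

# Textbook two-pass Pearson correlation.
two_pass_pearson <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

# Closed-form OLS via the normal equations (independent of stats::lm).
normal_equations_ols <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}
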