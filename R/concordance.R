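# Cross-tool agreement on retroelement locus calls: categorization,
# Cohen's kappa, Pearson correlation, and consensus selection.

CALL_LEVELS <- c("up", "down", "ns")

#' Categorize differential-expression results
#'
#' Converts log2 fold changes into `up` / `down` / `ns` calls:
#' `up` iff `padj < alpha` and `log2fc >= lfc_min`; `down` iff
#' `padj < alpha` and `log2fc <= -lfc_min`; everything else (including
#' missing `padj`) is `ns`. The fold-change bound is inclusive, the
#' significance bound strict.
#'
#' @param log2fc Numeric vector of log2 fold changes.
#' @param padj Numeric vector of adjusted p-values (`NA` allowed).
#' @param alpha Significance threshold, default 0.05.
#' @param lfc_min Minimum absolute log2 fold change, default 1.
#' @return A factor with levels `up`, `down`, `ns`.
#' @export
categorize <- function(log2fc, padj, alpha = 0.05, lfc_min = 1) {
  stopifnot(alpha > 0, lfc_min > 0)
  sig <- !is.na(padj) & padj < alpha & !is.na(log2fc)
  out <- rep("ns", length(log2fc))
  out[sig & log2fc >= lfc_min] <- "up"
  out[sig & log2fc <= -lfc_min] <- "down"
  factor(out, levels = CALL_LEVELS)
}

#' Cohen's kappa between two sets of categorical calls
#'
#' Unweighted multi-category kappa over the 3x3 confusion matrix:
#' `kappa = (P0 - Pe) / (1 - Pe)` with observed agreement `P0` (diagonal
#' mass) and chance agreement `Pe` (sum of products of row and column
#' marginals). Calls are matched by `feature_id`; features present in only
#' one list are excluded.
#'
#' @param calls_a,calls_b Data frames with columns `feature_id` and
#'   `category` (levels `up`, `down`, `ns`).
#' @return A list with `kappa`, `p0`, `pe`, `n` and a logical `degenerate`
#'   flag (both raters constant and identical, `Pe == 1`, kappa reported
#'   as 1).
#' @export
cohen_kappa <- function(calls_a, calls_b) {
  shared <- intersect(calls_a$feature_id, calls_b$feature_id)
  if (length(shared) < 2L) stop("fewer than 2 shared features between call sets")
  a <- factor(calls_a$category[match(shared, calls_a$feature_id)], CALL_LEVELS)
  b <- factor(calls_b$category[match(shared, calls_b$feature_id)], CALL_LEVELS)
  n <- length(shared)
  conf <- table(a, b)
  p0 <- sum(diag(conf)) / n
  pe <- sum(rowSums(conf) * colSums(conf)) / n^2
  if (pe >= 1) {
    return(list(kappa = 1, p0 = p0, pe = pe, n = n, degenerate = TRUE))
  }
  list(kappa = (p0 - pe) / (1 - pe), p0 = p0, pe = pe, n = n,
       degenerate = FALSE)
}

#' Pairwise inter-tool agreement
#'
#' For every unordered pair of tools: Pearson r and R-squared on the log2
#' fold changes of the shared features (non-missing in both), plus Cohen's
#' kappa on the categorized calls. The feature universe for each pair is the
#' intersection of feature ids quantified by both tools.
#'
#' @param tables Named list (one element per tool) of DE tables as returned
#'   by [read_de_table()].
#' @param alpha,lfc_min Categorization thresholds, see [categorize()].
#' @return A `data.frame` with one row per tool pair: `tool_a`, `tool_b`,
#'   `n_features`, `pearson_r`, `r_squared`, `kappa`, `p0`, `pe`,
#'   `computable`.
#' @export
pairwise_agreement <- function(tables, alpha = 0.05, lfc_min = 1) {
  stopifnot(is.list(tables), length(tables) >= 2L, !is.null(names(tables)))
  tools <- names(tables)
  pairs <- utils::combn(tools, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    ta <- tables[[pairs[1L, i]]]
    tb <- tables[[pairs[2L, i]]]
    shared <- intersect(ta$feature_id, tb$feature_id)
    ia <- match(shared, ta$feature_id)
    ib <- match(shared, tb$feature_id)
    ok <- !is.na(ta$log2fc[ia]) & !is.na(tb$log2fc[ib])
    out <- data.frame(tool_a = pairs[1L, i], tool_b = pairs[2L, i],
                      n_features = sum(ok), pearson_r = NA_real_,
                      r_squared = NA_real_, kappa = NA_real_,
                      p0 = NA_real_, pe = NA_real_, computable = FALSE,
                      stringsAsFactors = FALSE)
    if (sum(ok) < 3L) return(out)
    r <- cor(ta$log2fc[ia][ok], tb$log2fc[ib][ok], method = "pearson")
    kap <- cohen_kappa(
      data.frame(feature_id = shared,
                 category = categorize(ta$log2fc[ia], ta$padj[ia], alpha, lfc_min)),
      data.frame(feature_id = shared,
                 category = categorize(tb$log2fc[ib], tb$padj[ib], alpha, lfc_min))
    )
    out$pearson_r <- r
    out$r_squared <- r^2
    out$kappa <- kap$kappa
    out$p0 <- kap$p0
    out$pe <- kap$pe
    out$computable <- TRUE
    out
  })
  do.call(rbind, rows)
}

#' Consensus selection policy
#'
#' Two policies are supported, reflecting the two selection rules used for
#' the locus lists:
#' * `all_significant_two_lfc` — keep a locus significant (`padj < alpha`)
#'   in all tools whose fold change meets `|log2fc| >= lfc_min` in at least
#'   two of them;
#' * `anchor_plus_one` — keep a locus that passes the full threshold
#'   (`padj < alpha` and `|log2fc| >= lfc_min`) in the anchor tool and in at
#'   least one other tool.
#'
#' @param mode `"all_significant_two_lfc"` or `"anchor_plus_one"`.
#' @param alpha Significance threshold (strict), default 0.05.
#' @param lfc_min Fold-change threshold (inclusive), default 1.
#' @param anchor_tool Anchor tool name; required iff `mode ==
#'   "anchor_plus_one"`.
#' @return A `consensus_policy` list.
#' @export
consensus_policy <- function(mode = c("all_significant_two_lfc", "anchor_plus_one"),
                             alpha = 0.05, lfc_min = 1, anchor_tool = NULL) {
  mode <- match.arg(mode)
  stopifnot(alpha > 0, alpha < 1, lfc_min > 0)
  if (mode == "anchor_plus_one" && is.null(anchor_tool)) {
    stop("anchor_tool is required for mode 'anchor_plus_one'")
  }
  structure(list(mode = mode, alpha = alpha, lfc_min = lfc_min,
                 anchor_tool = anchor_tool),
            class = "consensus_policy")
}

#' Select consensus differentially expressed loci across tools
#'
#' Applies a [consensus_policy()] to per-tool DE tables. Direction is the
#' common sign of the significant tools' fold changes (anchor sign under
#' `anchor_plus_one`); features whose significant calls disagree in sign are
#' excluded and listed in `attr(x, "conflicts")`.
#'
#' @param tables Named list of DE tables (one per tool).
#' @param policy A [consensus_policy()].
#' @return A `data.frame` with columns `feature_id` and `direction`
#'   (`"up"`/`"down"`), ordered by feature id.
#' @export
consensus_select <- function(tables, policy) {
  stopifnot(inherits(policy, "consensus_policy"))
  tools <- names(tables)
  if (policy$mode == "anchor_plus_one" && !policy$anchor_tool %in% tools) {
    stop("anchor tool '", policy$anchor_tool, "' not among supplied tables: ",
         paste(tools, collapse = ", "))
  }
  ids <- sort(unique(unlist(lapply(tables, `[[`, "feature_id"))))
  lfc <- sapply(tables, function(t) t$log2fc[match(ids, t$feature_id)])
  padj <- sapply(tables, function(t) t$padj[match(ids, t$feature_id)])
  lfc <- matrix(lfc, nrow = length(ids), dimnames = list(ids, tools))
  padj <- matrix(padj, nrow = length(ids), dimnames = list(ids, tools))

  sig <- !is.na(padj) & padj < policy$alpha
  big <- !is.na(lfc) & abs(lfc) >= policy$lfc_min
  full <- sig & big

  if (policy$mode == "all_significant_two_lfc") {
    selected <- rowSums(sig) == length(tools) & rowSums(big) >= 2L
  } else {
    anchor <- policy$anchor_tool
    selected <- full[, anchor] & rowSums(full[, setdiff(tools, anchor), drop = FALSE]) >= 1L
  }

  conflicts <- character(0)
  direction <- rep(NA_character_, length(ids))
  for (i in which(selected)) {
    signs <- sign(lfc[i, sig[i, ] & !is.na(lfc[i, ])])
    signs <- unique(signs[signs != 0])
    if (length(signs) != 1L) {
      conflicts <- c(conflicts, ids[i])
      selected[i] <- FALSE
      next
    }
    if (policy$mode == "anchor_plus_one") {
      direction[i] <- if (lfc[i, policy$anchor_tool] > 0) "up" else "down"
    } else {
      direction[i] <- if (signs > 0) "up" else "down"
    }
  }
  out <- data.frame(feature_id = ids[selected],
                    direction = direction[selected],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "conflicts") <- conflicts
  out
}

#' Exclusive Venn regions of per-subtype feature sets
#'
#' Computes all `2^k - 1` exclusive membership regions of 2-4 sets. Regions
#' are pairwise disjoint and their union equals the union of the inputs.
#'
#' @param sets Named list of character vectors (feature ids per subtype).
#' @return A named list of character vectors; region names join the member
#'   set names with `"&"` (e.g. `"CMS1&CMS3"` holds ids in exactly those
#'   two sets).
#' @export
subtype_venn <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2L, length(sets) <= 4L,
            !is.null(names(sets)))
  ids <- sort(unique(unlist(sets)))
  member <- vapply(sets, function(s) ids %in% s, logical(length(ids)))
  member <- matrix(member, nrow = length(ids), dimnames = list(ids, names(sets)))
  key <- apply(member, 1L, function(m) paste(names(sets)[m], collapse = "&"))
  combos <- unlist(lapply(seq_along(sets), function(k) {
    apply(utils::combn(names(sets), k), 2L, paste, collapse = "&")
  }))
  regions <- setNames(vector("list", length(combos)), combos)
  for (cb in combos) regions[[cb]] <- ids[key == cb]
  regions
}
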