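# Per-subtype orchestration: concordance -> consensus -> association ->
# methylation coupling, with deterministic TSV exports and a JSON
# metadata sidecar.

#' Pipeline run configuration
#'
#' @param subtypes Named list; each element describes one subtype's inputs:
#'   `de_locus` (named character vector of per-tool locus DE TSV paths),
#'   `de_gene` (gene DE TSV path), `genes_gtf`, `loci_bed`, `meth`,
#'   `manifest` (paths).
#' @param policy A [consensus_policy()].
#' @param filter A [filter_config()].
#' @param gene_pair_window,locus_pair_window,nearby_window Pairing and
#'   flanking windows in bp (defaults 3000, 10000, 50000).
#' @param alpha,lfc_min Differential-expression thresholds used for
#'   agreement categorization and link annotation.
#' @param anchor_tool Tool whose DE table supplies the locus expression
#'   log2FC for coupling; defaults to the policy's anchor or the first
#'   tool.
#' @param qpcr Optional qPCR CSV path (cohort-level, not per subtype).
#' @param seed Integer seed recorded in the metadata sidecar.
#' @return A `run_config` list.
#' @export
run_config <- function(subtypes, policy = consensus_policy(),
                       filter = filter_config(),
                       gene_pair_window = 3000L, locus_pair_window = 10000L,
                       nearby_window = 50000L, alpha = 0.05, lfc_min = 1,
                       anchor_tool = NULL, qpcr = NULL, seed = 1L) {
  stopifnot(is.list(subtypes), length(subtypes) >= 1L, !is.null(names(subtypes)))
  structure(list(subtypes = subtypes, policy = policy, filter = filter,
                 gene_pair_window = gene_pair_window,
                 locus_pair_window = locus_pair_window,
                 nearby_window = nearby_window, alpha = alpha,
                 lfc_min = lfc_min, anchor_tool = anchor_tool, qpcr = qpcr,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis for one subtype
#'
#' Executes, in order: cross-tool agreement, consensus locus selection,
#' host-gene and flanking-gene association, CpG-gene and CpG-locus pairing
#' with filtering, Spearman correlation and the interaction regressions.
#' One TSV per result class is written to `out_dir/<subtype>/` together
#' with a `metadata.json` sidecar recording the configuration, seed, and
#' every filter's kept/dropped counts.
#'
#' @param cfg A [run_config()].
#' @param subtype Name of the subtype to run (must be in `cfg$subtypes`).
#' @param out_dir Output directory root.
#' @return A list of in-memory results (`agreement`, `consensus`,
#'   `host_links`, `nearby_links`, `gene_pairs`, `locus_pairs`,
#'   `correlations`, `regressions`, `counts`), invisibly.
#' @export
run_subtype <- function(cfg, subtype, out_dir) {
  stopifnot(inherits(cfg, "run_config"), subtype %in% names(cfg$subtypes))
  st <- cfg$subtypes[[subtype]]
  sub_dir <- file.path(out_dir, subtype)
  dir.create(sub_dir, showWarnings = FALSE, recursive = TRUE)

  missing_tools <- names(st$de_locus)[!file.exists(unlist(st$de_locus))]
  if (length(missing_tools)) {
    stop("missing locus DE table(s) for tool(s): ",
         paste(missing_tools, collapse = ", "))
  }
  de_tables <- Map(function(p, tool) read_de_table(p, tool, subtype),
                   st$de_locus, names(st$de_locus))
  gene_de <- read_de_table(st$de_gene, "generic", subtype)

  agreement <- pairwise_agreement(de_tables, cfg$alpha, cfg$lfc_min)
  consensus <- consensus_select(de_tables, cfg$policy)

  genes <- read_gtf(st$genes_gtf)
  loci <- read_locus_bed(st$loci_bed)
  anchor <- cfg$anchor_tool
  if (is.null(anchor)) anchor <- cfg$policy$anchor_tool
  if (is.null(anchor)) anchor <- names(de_tables)[1L]
  locus_de <- de_tables[[anchor]]

  de_loci <- loci[loci$feature_id %in% consensus$feature_id, , drop = FALSE]
  host <- annotate_links(find_host_genes(de_loci, genes), locus_de, gene_de)
  nearby <- annotate_links(find_nearby_genes(de_loci, genes, cfg$nearby_window),
                           locus_de, gene_de)

  sites <- read_methylation_table(st$meth, st$manifest)

  # Gene-side coupling uses the genes that harbour consensus loci.
  host_genes <- genes[genes$feature_id %in% unique(host$gene_id), , drop = FALSE]
  gene_pairs_all <- pair_cpg_gene(sites, host_genes, cfg$gene_pair_window)
  gene_pairs <- filter_pairs(gene_pairs_all, gene_de, cfg$filter)
  locus_pairs_all <- pair_cpg_locus(sites, loci, cfg$locus_pair_window)
  locus_pairs <- filter_pairs(locus_pairs_all, locus_de, cfg$filter,
                              consensus = consensus$feature_id)

  cor_row <- function(pairs, kind) {
    if (nrow(pairs) < 3L) {
      return(data.frame(subtype = subtype, pair_kind = kind, rho = NA_real_,
                        pvalue = NA_real_, n_pairs = nrow(pairs),
                        n_unique_cpgs = length(unique(pairs$cpg_id)),
                        n_unique_partners = length(unique(pairs$partner_id)),
                        stringsAsFactors = FALSE))
    }
    s <- spearman_coupling(pairs)
    data.frame(subtype = subtype, pair_kind = kind, rho = s$rho,
               pvalue = s$pvalue, n_pairs = s$n_pairs,
               n_unique_cpgs = s$n_unique_cpgs,
               n_unique_partners = s$n_unique_partners,
               stringsAsFactors = FALSE)
  }
  correlations <- rbind(cor_row(gene_pairs, "cpg_gene"),
                        cor_row(locus_pairs, "cpg_locus"))

  reg_locus <- fit_locus_model(locus_pairs)
  reg_gene <- fit_gene_model(gene_pairs)
  reg_tsv <- function(res) {
    if (!res$applicable) {
      return(data.frame(model = res$model, applicable = FALSE,
                        reason = res$inapplicability_reason,
                        beta = NA_character_, term = NA_character_,
                        estimate = NA_real_, se = NA_real_, t = NA_real_,
                        pvalue = NA_real_, stringsAsFactors = FALSE))
    }
    cbind(data.frame(model = res$model, applicable = TRUE, reason = NA_character_,
                     stringsAsFactors = FALSE),
          res$coefficients)
  }

  counts <- list(
    n_loci_quantified = length(unique(unlist(lapply(de_tables, `[[`, "feature_id")))),
    n_consensus_loci = nrow(consensus),
    n_direction_conflicts = length(attr(consensus, "conflicts")),
    n_host_links = nrow(host),
    n_nearby_links = nrow(nearby),
    n_cpg_sites = nrow(sites),
    n_cpg_sites_dropped = attr(sites, "n_dropped"),
    gene_pairs_before_filter = nrow(gene_pairs_all),
    gene_pairs_after_filter = nrow(gene_pairs),
    locus_pairs_before_filter = nrow(locus_pairs_all),
    locus_pairs_after_filter = nrow(locus_pairs)
  )

  write_tsv(agreement, file.path(sub_dir, "agreement.tsv"))
  write_tsv(consensus, file.path(sub_dir, "consensus.tsv"))
  write_tsv(host, file.path(sub_dir, "host_links.tsv"))
  write_tsv(nearby, file.path(sub_dir, "nearby_links.tsv"))
  write_tsv(gene_pairs, file.path(sub_dir, "gene_pairs.tsv"))
  write_tsv(locus_pairs, file.path(sub_dir, "locus_pairs.tsv"))
  write_tsv(correlations, file.path(sub_dir, "correlation_summary.tsv"))
  write_tsv(reg_tsv(reg_locus), file.path(sub_dir, "regression_locus.tsv"))
  write_tsv(reg_tsv(reg_gene), file.path(sub_dir, "regression_gene.tsv"))
  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("retromethyl")),
         subtype = subtype, seed = cfg$seed,
         inputs = st,
         policy = unclass(cfg$policy), filter = unclass(cfg$filter),
         windows = list(gene_pair = cfg$gene_pair_window,
                        locus_pair = cfg$locus_pair_window,
                        nearby = cfg$nearby_window),
         anchor_tool = anchor, counts = counts),
    file.path(sub_dir, "metadata.json"), auto_unbox = TRUE, digits = NA,
    null = "null")

  invisible(list(agreement = agreement, consensus = consensus,
                 host_links = host, nearby_links = nearby,
                 gene_pairs = gene_pairs, locus_pairs = locus_pairs,
                 correlations = correlations,
                 regressions = list(locus = reg_locus, gene = reg_gene),
                 counts = counts))
}

#' Run the pipeline for all configured subtypes
#'
#' Subtypes run independently; a failure in one is captured as a structured
#' error and the others continue. qPCR summarization runs once at the
#' cohort level when a Ct table is configured.
#'
#' @param cfg A [run_config()].
#' @param out_dir Output directory root; one subdirectory per subtype.
#' @return A list with `results` (per subtype), `errors` (named character
#'   vector of failure messages, empty on full success), and `qpcr`
#'   (summary or `NULL`), invisibly.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  errors <- character(0)
  for (st in names(cfg$subtypes)) {
    res <- tryCatch(run_subtype(cfg, st, out_dir),
                    error = function(e) e)
    if (inherits(res, "error")) {
      errors[[st]] <- conditionMessage(res)
    } else {
      results[[st]] <- res
    }
  }
  qpcr_res <- NULL
  if (!is.null(cfg$qpcr)) {
    qpcr_res <- qpcr_summarize(qpcr_fold_change(read_qpcr(cfg$qpcr)))
    write_tsv(qpcr_res$summary, file.path(out_dir, "qpcr_summary.tsv"))
    write_tsv(qpcr_res$per_patient, file.path(out_dir, "qpcr_per_patient.tsv"))
  }
  if (length(errors)) {
    warning("subtype(s) failed: ",
            paste(sprintf("%s (%s)", names(errors), errors), collapse = "; "))
  }
  invisible(list(results = results, errors = errors, qpcr = qpcr_res))
}
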