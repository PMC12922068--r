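# Ground-truth generators for every pipeline input class: genomic layouts,
# per-tool DE tables with controlled agreement, coupled methylation tables,
# and paired qPCR cohorts. All generators are deterministic under the
# configured seed.

#' Simulation configuration
#'
#' Defaults emulate the study conditions the pipeline was built for:
#' three quantification tools with an analytic inter-tool Pearson
#' correlation of 0.9 on locus log2 fold changes, negative coupling between
#' CpG methylation and locus expression (slope -0.6), positive
#' methylation-expression coupling for genes with a sign-flipping promoter
#' interaction (+0.4 / -0.9), and a paired qPCR cohort with mean
#' delta-delta-Ct -0.92 +/- 1.16 (env) and -0.52 +/- 1.30 (gag).
#'
#' @param seed Integer seed; identical configurations give byte-identical
#'   outputs.
#' @param n_genes,n_loci,n_cpgs Feature counts.
#' @param chrom Synthetic chromosome name.
#' @param chrom_length Chromosome length in bp; placement fails with an
#'   error if the requested features cannot be packed.
#' @param frac_intragenic_loci,frac_nearby_loci Fractions of loci placed
#'   strictly inside a gene or within 1-50,000 bp of one; the remainder is
#'   isolated (> 50,000 bp from every gene).
#' @param de_effect_sd Spread of non-core true log2 fold changes.
#' @param frac_true_de Fraction of truly differentially expressed features.
#' @param frac_core_de Fraction of true-DE loci in the "core" subset whose
#'   absolute effect is guaranteed >= 1.5.
#' @param tool_noise_sd Per-tool measurement noise SD on log2FC; ignored
#'   when `target_r` is set.
#' @param target_r Analytic inter-tool Pearson correlation
#'   `Var(true) / (Var(true) + sd^2)`; when non-`NULL` the tool noise SD is
#'   derived from the realized variance of true effects.
#' @param coupling_beta_locus Named vector `beta0`..`beta3` of true
#'   locus-model coefficients.
#' @param coupling_beta_gene Named vector `beta0`..`beta5` of true
#'   gene-model coefficients.
#' @param noise_sd Residual SD of the coupling forward model.
#' @param promoter_frac Fraction of gene-linked CpGs placed in the TSS200
#'   promoter zone.
#' @param same_strand_frac Probability that a locus shares its partner
#'   gene's strand.
#' @param frac_coupled_cpgs Fraction of CpGs with differential methylation
#'   beyond the 0.1 threshold (the rest are null sites).
#' @param n_patients qPCR cohort size (paired tumor/normal).
#' @param qpcr_mean_ddct,qpcr_sd Named per-target vectors of the true
#'   delta-delta-Ct mean and SD.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 120L, n_loci = 100L, n_cpgs = 800L,
                       chrom = "chrS1", chrom_length = 60e6,
                       frac_intragenic_loci = 0.4, frac_nearby_loci = 0.3,
                       de_effect_sd = 1.5, frac_true_de = 0.3,
                       frac_core_de = 0.6,
                       tool_noise_sd = 0.42, target_r = 0.9,
                       coupling_beta_locus = c(beta0 = 0, beta1 = -0.6,
                                               beta2 = 0, beta3 = 0),
                       coupling_beta_gene = c(beta0 = 0, beta1 = 0.4,
                                              beta2 = 0, beta3 = 0,
                                              beta4 = 0, beta5 = -0.9),
                       noise_sd = 0.3,
                       promoter_frac = 0.25, same_strand_frac = 0.5,
                       frac_coupled_cpgs = 0.8,
                       n_patients = 20L,
                       qpcr_mean_ddct = c(env = -0.92, gag = -0.52),
                       qpcr_sd = c(env = 1.16, gag = 1.30)) {
  fracs <- c(frac_intragenic_loci, frac_nearby_loci, frac_true_de,
             frac_core_de, promoter_frac, same_strand_frac, frac_coupled_cpgs)
  stopifnot(all(fracs >= 0), all(fracs <= 1),
            frac_intragenic_loci + frac_nearby_loci <= 1,
            de_effect_sd >= 0, tool_noise_sd >= 0, noise_sd >= 0,
            seed == as.integer(seed))
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a genomic layout of genes and retroelement loci
#'
#' Places non-overlapping genes along one synthetic chromosome with
#' intergenic gaps wide enough that each locus's intended relation
#' (intragenic / nearby / isolated) is unambiguous, and assigns strands so
#' that locus-gene strand agreement hits `same_strand_frac` in expectation.
#'
#' @param cfg A [sim_config()].
#' @param dir Optional output directory; when given, `genes.gtf` and
#'   `loci.bed` are written there.
#' @return A list: `genes` and `loci` feature tables, a `truth` table
#'   (locus id, intended relation, partner gene, intended distance), and
#'   file `paths` when `dir` was given.
#' @export
simulate_layout <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 11L)
  n_genes <- cfg$n_genes
  gene_len <- round(runif(n_genes, 2000, 20000))
  gaps <- round(runif(n_genes, 150000, 250000))
  starts <- 100000 + cumsum(gaps) + cumsum(c(0, gene_len[-n_genes]))
  ends <- starts + gene_len - 1L
  if (max(ends) + 60000 > cfg$chrom_length) {
    stop("infeasible packing: ", n_genes, " genes need ",
         max(ends) + 60000, " bp but chrom_length is ", cfg$chrom_length)
  }
  biotypes <- sample(c("protein_coding", "lncRNA", "pseudogene"),
                     n_genes, replace = TRUE, prob = c(0.6, 0.3, 0.1))
  genes <- genomic_features(
    feature_id = sprintf("GENE%03d", seq_len(n_genes)),
    kind = "gene", chrom = cfg$chrom, start = starts, end = ends,
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    biotype = biotypes
  )

  n_intra <- round(cfg$frac_intragenic_loci * cfg$n_loci)
  n_near <- round(cfg$frac_nearby_loci * cfg$n_loci)
  n_iso <- cfg$n_loci - n_intra - n_near
  relation <- c(rep("intragenic", n_intra), rep("nearby", n_near),
                rep("isolated", n_iso))
  locus_len <- round(runif(cfg$n_loci, 500, 9000))
  locus_start <- integer(cfg$n_loci)
  partner <- rep(NA_character_, cfg$n_loci)
  intended_distance <- rep(NA_integer_, cfg$n_loci)
  strand <- character(cfg$n_loci)

  for (i in seq_len(cfg$n_loci)) {
    if (relation[i] == "intragenic") {
      ok <- which(gene_len > locus_len[i] + 2L)
      g <- ok[sample.int(length(ok), 1L)]
      locus_start[i] <- sample(seq(genes$start[g] + 1L,
                                   genes$end[g] - locus_len[i]), 1L)
      partner[i] <- genes$feature_id[g]
      intended_distance[i] <- 0L
    } else if (relation[i] == "nearby") {
      g <- sample(n_genes, 1L)
      gap <- sample(45000L, 1L)
      locus_start[i] <- genes$end[g] + gap + 1L
      partner[i] <- genes$feature_id[g]
      intended_distance[i] <- gap
    } else {
      g <- sample(n_genes - 1L, 1L)  # place mid-gap, > 50 kb from both genes
      lo <- genes$end[g] + 55001L
      hi <- genes$start[g + 1L] - 55001L - locus_len[i]
      if (hi < lo) stop("infeasible packing for an isolated locus")
      locus_start[i] <- sample(seq(lo, hi), 1L)
    }
    anchor_strand <- if (is.na(partner[i])) {
      sample(c("+", "-"), 1L)
    } else {
      genes$strand[match(partner[i], genes$feature_id)]
    }
    same <- runif(1) < cfg$same_strand_frac
    strand[i] <- if (same) anchor_strand else setdiff(c("+", "-"), anchor_strand)
  }
  loci <- genomic_features(
    feature_id = sprintf("HML-2_S%02d", seq_len(cfg$n_loci)),
    kind = "locus", chrom = cfg$chrom,
    start = locus_start, end = locus_start + locus_len - 1L,
    strand = strand
  )
  truth <- data.frame(locus_id = loci$feature_id, relation = relation,
                      partner_gene = partner,
                      intended_distance = intended_distance,
                      stringsAsFactors = FALSE)
  out <- list(genes = genes, loci = loci, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    out$paths <- c(genes = file.path(dir, "genes.gtf"),
                   loci = file.path(dir, "loci.bed"))
    write_features_gtf(genes, out$paths[["genes"]])
    write_features_bed(loci, out$paths[["loci"]])
  }
  out
}

sim_true_effects <- function(n, frac_de, frac_core, effect_sd) {
  is_de <- runif(n) < frac_de
  is_core <- is_de & runif(n) < frac_core
  eff <- numeric(n)
  soft <- is_de & !is_core
  eff[soft] <- rnorm(sum(soft), 0, effect_sd)
  eff[is_core] <- sample(c(-1, 1), sum(is_core), replace = TRUE) *
    runif(sum(is_core), 1.5, 3)
  list(effect = eff, is_de = is_de, is_core = is_core)
}

# Core features are observed with bounded measurement error (|noise| < 0.5,
# a truncated Normal), so each tool individually sees the correct sign and
# |log2FC| >= 1: the recovery floor for closed-loop consensus tests.
CORE_NOISE_BOUND <- 0.5

rtruncnorm0 <- function(n, sd, bound) {
  if (sd == 0) return(numeric(n))
  lo <- pnorm(-bound, 0, sd)
  qnorm(runif(n, lo, 1 - lo), 0, sd)
}

# Variance of a Normal(0, sd) truncated to (-bound, bound).
truncnorm_var <- function(sd, bound) {
  if (sd == 0) return(0)
  a <- bound / sd
  sd^2 * (1 - 2 * a * stats::dnorm(a) / (2 * pnorm(a) - 1))
}

# Mean per-feature noise variance given the core fraction, and the noise SD
# that hits a target analytic inter-tool correlation r = v_true/(v_true + v).
mixture_noise_var <- function(sd, frac_core) {
  (1 - frac_core) * sd^2 + frac_core * truncnorm_var(sd, CORE_NOISE_BOUND)
}

solve_noise_sd <- function(v_true, target_r, frac_core) {
  v_target <- v_true * (1 - target_r) / target_r
  if (v_target <= 0) return(0)
  stats::uniroot(function(s) mixture_noise_var(s, frac_core) - v_target,
                 lower = 1e-9, upper = 100, tol = 1e-12)$root
}

de_table_from_effects <- function(ids, effects, noise_sd, sensitivity = 0.9) {
  effect <- effects$effect
  n <- length(effect)
  noise <- rnorm(n, 0, noise_sd)
  noise[effects$is_core] <- rtruncnorm0(sum(effects$is_core), noise_sd,
                                        CORE_NOISE_BOUND)
  obs <- effect + noise
  p <- if (noise_sd > 0) {
    2 * pnorm(-abs(obs) / noise_sd)
  } else {
    ifelse(effect != 0, 0, 1)
  }
  # true positives are called with the stated per-tool sensitivity
  # (always, for the core subset)
  hit <- effects$is_de & (effects$is_core | runif(n) < sensitivity)
  p[hit] <- runif(sum(hit), 0, 1e-6)
  data.frame(feature_id = ids, log2FoldChange = obs, pvalue = p,
             padj = p.adjust(p, "BH"), stringsAsFactors = FALSE)
}

#' Simulate per-tool differential-expression tables
#'
#' Each truly-DE locus receives a true log2FC (the core subset with
#' guaranteed `|effect| >= 1.5`); each pseudo-tool observes the true value
#' plus independent Normal noise, with p-values from the corresponding
#' z-test, BH-adjusted, and true positives additionally called at a stated
#' per-tool sensitivity (0.9; always for the core subset). Core loci are
#' observed with bounded error (`|noise| < 0.5`, a truncated Normal), so
#' every tool sees them with the correct sign and `|log2FC| >= 1` — the
#' recovery floor for closed-loop consensus tests. Under this additive-noise
#' model the analytic inter-tool Pearson correlation is
#' `Var(true) / (Var(true) + E[Var(noise)])`, recorded in the truth
#' metadata; when `cfg$target_r` is set the noise SD is solved to hit it on
#' the realized effects. A single generic gene DE table is produced
#' alongside.
#'
#' @param cfg A [sim_config()].
#' @param layout Output of [simulate_layout()].
#' @param dir Optional output directory for `de_toolA.tsv` ..
#'   `de_toolC.tsv` and `de_genes.tsv`.
#' @return A list: `tables` (named list toolA/toolB/toolC of DE tables in
#'   reader format), `gene_table`, `truth` (per-feature effects and flags,
#'   plus `analytic_r` and `tool_noise_sd`), and `paths` when written.
#' @export
simulate_de_tables <- function(cfg, layout, dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 22L)
  loc <- sim_true_effects(cfg$n_loci, cfg$frac_true_de, cfg$frac_core_de,
                          cfg$de_effect_sd)
  sdn <- cfg$tool_noise_sd
  if (!is.null(cfg$target_r)) {
    sdn <- solve_noise_sd(var(loc$effect), cfg$target_r, mean(loc$is_core))
  }
  tools <- c("toolA", "toolB", "toolC")
  raw <- lapply(tools, function(t) {
    de_table_from_effects(layout$loci$feature_id, loc, sdn)
  })
  names(raw) <- tools

  gen <- sim_true_effects(cfg$n_genes, cfg$frac_true_de, cfg$frac_core_de,
                          cfg$de_effect_sd)
  gene_raw <- de_table_from_effects(layout$genes$feature_id, gen, 0.1)

  as_de <- function(tab, tool) {
    data.frame(feature_id = tab$feature_id, log2fc = tab$log2FoldChange,
               pvalue = tab$pvalue, padj = tab$padj, tool = tool,
               subtype = NA_character_, stringsAsFactors = FALSE)
  }
  out <- list(
    tables = Map(as_de, raw, tools),
    gene_table = as_de(gene_raw, "generic"),
    truth = list(
      loci = data.frame(feature_id = layout$loci$feature_id,
                        true_log2fc = loc$effect, is_de = loc$is_de,
                        is_core = loc$is_core, stringsAsFactors = FALSE),
      genes = data.frame(feature_id = layout$genes$feature_id,
                         true_log2fc = gen$effect, is_de = gen$is_de,
                         stringsAsFactors = FALSE),
      tool_noise_sd = sdn,
      analytic_r = var(loc$effect) /
        (var(loc$effect) + mixture_noise_var(sdn, mean(loc$is_core)))
    )
  )
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(setNames(file.path(dir, sprintf("de_%s.tsv", tools)), tools),
               genes = file.path(dir, "de_genes.tsv"))
    for (t in tools) write_tsv(raw[[t]], paths[[t]])
    write_tsv(gene_raw, paths[["genes"]])
    out$paths <- paths
  }
  out
}

#' Simulate CpG-partner pairs from the coupling forward model
#'
#' Draws design variables directly and generates the response from the
#' stated interaction model, for parameter-recovery and power checks.
#' For `kind = "locus"`: `Y = b0 + b1*X1 + b2*X2 + b3*X1*X2 + e`;
#' for `kind = "gene"` the promoter terms `b3*X3 + b5*X1*X3` are added
#' (coefficient vector `beta0`..`beta5`). `X1 ~ N(0, 1)`,
#' `X2 ~ Bernoulli(same_strand_frac)`, `X3 ~ Bernoulli(promoter_frac)`,
#' `e ~ N(0, noise_sd)`. Significance columns are set so every pair passes
#' the default filters.
#'
#' @param n Number of pairs.
#' @param beta Coefficient vector: `beta0`..`beta3` (locus) or
#'   `beta0`..`beta5` (gene).
#' @param noise_sd Residual SD.
#' @param same_strand_frac,promoter_frac Bernoulli rates of `X2` / `X3`.
#' @param kind `"locus"` or `"gene"`.
#' @param seed Optional integer seed.
#' @return A pair `data.frame` ready for [spearman_coupling()] /
#'   [fit_locus_model()] / [fit_gene_model()].
#' @export
simulate_pairs <- function(n, beta, noise_sd = 0.3, same_strand_frac = 0.5,
                           promoter_frac = 0.3, kind = c("locus", "gene"),
                           seed = NULL) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  b <- setNames(rep(0, 6), paste0("beta", 0:5))
  b[names(beta)] <- beta
  X1 <- rnorm(n)
  X2 <- rbinom(n, 1L, same_strand_frac)
  X3 <- if (kind == "gene") rbinom(n, 1L, promoter_frac) else rep(0L, n)
  e <- rnorm(n, 0, noise_sd)
  Y <- if (kind == "locus") {
    b["beta0"] + b["beta1"] * X1 + b["beta2"] * X2 + b["beta3"] * X1 * X2 + e
  } else {
    b["beta0"] + b["beta1"] * X1 + b["beta2"] * X2 + b["beta3"] * X3 +
      b["beta4"] * X1 * X2 + b["beta5"] * X1 * X3 + e
  }
  out <- data.frame(
    pair_kind = if (kind == "locus") "cpg_locus" else "cpg_gene",
    cpg_id = sprintf("cg%06d", seq_len(n)),
    partner_id = sprintf("P%04d", seq_len(n)),
    X1 = X1, X2 = X2, Y = unname(Y),
    distance_bp = 0L,
    meth_pvalue = 1e-6, meth_padj = 1e-5,
    expr_pvalue = 1e-6, expr_padj = 1e-5,
    stringsAsFactors = FALSE
  )
  if (kind == "gene") out$X3 <- X3
  out
}

#' Simulate a differential-methylation table and CpG manifest
#'
#' Places CpGs inside or near the layout's loci and genes (promoter CpGs in
#' the strand-aware TSS200 zone, 200 bp upstream of the TSS). Coupled CpGs
#' get a methylation log2FC consistent with their partner's true expression
#' log2FC under the coupling forward model (obtained by inverting the model
#' and adding noise), so methylation and expression tables jointly carry
#' the configured coupling; null CpGs get near-zero effects and uniform
#' p-values.
#'
#' @param cfg A [sim_config()].
#' @param layout Output of [simulate_layout()].
#' @param de Output of [simulate_de_tables()] (supplies partner true
#'   effects).
#' @param dir Optional output directory for `meth.tsv` and `manifest.tsv`.
#' @return A list: `sites` (reader-format CpG table), `meth`/`manifest`
#'   raw tables, `truth` (per-CpG partner, coupling flag), and `paths`
#'   when written.
#' @export
simulate_methylation <- function(cfg, layout, de, dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 33L)
  n <- cfg$n_cpgs
  n_locus_cpg <- floor(n / 2)
  partner_kind <- c(rep("locus", n_locus_cpg), rep("gene", n - n_locus_cpg))
  genes <- layout$genes
  loci <- layout$loci
  # gene-linked CpGs concentrate on locus-hosting genes, mirroring a
  # methylation analysis restricted to retroelement-containing genes
  host_idx <- which(genes$feature_id %in%
                      layout$truth$partner_gene[layout$truth$relation == "intragenic"])
  if (!length(host_idx)) host_idx <- seq_len(nrow(genes))
  b_loc <- setNames(rep(0, 6), paste0("beta", 0:5))
  b_loc[names(cfg$coupling_beta_locus)] <- cfg$coupling_beta_locus
  b_gen <- setNames(rep(0, 6), paste0("beta", 0:5))
  b_gen[names(cfg$coupling_beta_gene)] <- cfg$coupling_beta_gene

  position <- integer(n)
  partner_id <- character(n)
  promoter <- logical(n)
  coupled <- runif(n) < cfg$frac_coupled_cpgs
  X1 <- numeric(n)
  for (i in seq_len(n)) {
    if (partner_kind[i] == "locus") {
      g <- sample(nrow(loci), 1L)
      position[i] <- sample(seq(max(1L, loci$start[g] - 8000L),
                                loci$end[g] + 8000L), 1L)
      partner_id[i] <- loci$feature_id[g]
      pstrand <- loci$strand[g]
      true_y <- de$truth$loci$true_log2fc[g]
      bb <- b_loc
      x3 <- 0L
    } else {
      g <- host_idx[sample.int(length(host_idx), 1L)]
      promoter[i] <- runif(1) < cfg$promoter_frac
      if (promoter[i]) {
        position[i] <- if (genes$strand[g] == "+") {
          sample(seq(genes$start[g] - 200L, genes$start[g] - 1L), 1L)
        } else {
          sample(seq(genes$end[g] + 1L, genes$end[g] + 200L), 1L)
        }
      } else {
        position[i] <- sample(seq(max(1L, genes$start[g] - 2500L),
                                  genes$end[g] + 2500L), 1L)
      }
      partner_id[i] <- genes$feature_id[g]
      pstrand <- genes$strand[g]
      true_y <- de$truth$genes$true_log2fc[g]
      bb <- b_gen
      x3 <- as.integer(promoter[i])
    }
    x2 <- as.integer(pstrand == "+")  # probes carry no strand: treated as '+'
    denom <- bb["beta1"] + bb["beta4"] * x2 + bb["beta5"] * x3
    if (coupled[i] && abs(denom) > 1e-8) {
      X1[i] <- (true_y - bb["beta0"] - bb["beta2"] * x2 - bb["beta3"] * x3) /
        denom + rnorm(1, 0, cfg$noise_sd / max(abs(denom), 0.2))
    } else {
      coupled[i] <- FALSE
      X1[i] <- rnorm(1, 0, 0.04)
    }
  }
  p <- ifelse(coupled & abs(X1) > 0.1, runif(n, 0, 0.005), runif(n, 0.1, 1))
  beta_normal <- runif(n, 0.2, 0.8)
  beta_tumor <- pmin(pmax(beta_normal + 0.15 * X1, 0), 1)

  cpg_id <- sprintf("cg%06d", seq_len(n))
  meth <- data.frame(cpg_id = cpg_id, log2FoldChange = X1, pvalue = p,
                     padj = p.adjust(p, "BH"), beta_tumor = beta_tumor,
                     beta_normal = beta_normal, stringsAsFactors = FALSE)
  tss200 <- ifelse(promoter, partner_id, "")
  manifest <- data.frame(cpg_id = cpg_id, chrom = cfg$chrom,
                         position = position, strand = "+",
                         tss200 = tss200, stringsAsFactors = FALSE)
  sites <- data.frame(cpg_id = cpg_id, chrom = cfg$chrom,
                      position = position, strand = "+",
                      strand_known = TRUE,
                      meth_log2fc = X1, pvalue = meth$pvalue,
                      padj = meth$padj, beta_tumor = beta_tumor,
                      beta_normal = beta_normal, stringsAsFactors = FALSE)
  sites$promoter_of <- lapply(tss200, function(x) x[nzchar(x)])
  out <- list(sites = sites, meth = meth, manifest = manifest,
              truth = data.frame(cpg_id = cpg_id, partner_kind = partner_kind,
                                 partner_id = partner_id, coupled = coupled,
                                 promoter = promoter, stringsAsFactors = FALSE))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    out$paths <- c(meth = file.path(dir, "meth.tsv"),
                   manifest = file.path(dir, "manifest.tsv"))
    write_tsv(meth, out$paths[["meth"]])
    write_tsv(manifest, out$paths[["manifest"]])
  }
  out
}

#' Simulate a paired tumor/normal qPCR cohort
#'
#' Per patient and target, the normal-tissue delta-Ct is drawn around 5
#' cycles, the tumor delta-Ct adds a delta-delta-Ct drawn from
#' `N(qpcr_mean_ddct[target], qpcr_sd[target])`, and reference Cts sit near
#' 20 cycles.
#'
#' @param cfg A [sim_config()].
#' @param dir Optional output directory for `qpcr.csv`.
#' @return A list: `measurements` (reader-format table), `truth` (the true
#'   per-target means/SDs), and `path` when written.
#' @export
simulate_qpcr <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 44L)
  targets <- names(cfg$qpcr_mean_ddct)
  rows <- list()
  for (tg in targets) {
    dct_normal <- rnorm(cfg$n_patients, 5, 1)
    ddct <- rnorm(cfg$n_patients, cfg$qpcr_mean_ddct[[tg]], cfg$qpcr_sd[[tg]])
    for (tissue in c("normal", "tumor")) {
      ref <- rnorm(cfg$n_patients, 20, 0.3)
      dct <- if (tissue == "normal") dct_normal else dct_normal + ddct
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = sprintf("PT%02d", seq_len(cfg$n_patients)),
        tissue = tissue, target = tg,
        ct_target = ref + dct, ct_reference = ref,
        stringsAsFactors = FALSE)
    }
  }
  measurements <- do.call(rbind, rows)
  rownames(measurements) <- NULL
  out <- list(measurements = measurements,
              truth = list(mean_ddct = cfg$qpcr_mean_ddct,
                           sd_ddct = cfg$qpcr_sd))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    out$path <- file.path(dir, "qpcr.csv")
    write.csv(measurements, out$path, row.names = FALSE, quote = FALSE)
  }
  out
}

#' Generate a complete synthetic data set
#'
#' Runs all generators under one configuration and (optionally) writes
#' every pipeline input plus a machine-readable `truth.json` to `dir`.
#'
#' @param cfg A [sim_config()].
#' @param dir Optional output directory.
#' @return A list with `layout`, `de`, `meth`, `qpcr` generator outputs and
#'   `paths`.
#' @export
simulate_all <- function(cfg = sim_config(), dir = NULL) {
  layout <- simulate_layout(cfg, dir)
  de <- simulate_de_tables(cfg, layout, dir)
  meth <- simulate_methylation(cfg, layout, de, dir)
  qpcr <- simulate_qpcr(cfg, dir)
  out <- list(layout = layout, de = de, meth = meth, qpcr = qpcr)
  if (!is.null(dir)) {
    truth_path <- file.path(dir, "truth.json")
    jsonlite::write_json(
      list(seed = cfg$seed,
           analytic_r = de$truth$analytic_r,
           tool_noise_sd = de$truth$tool_noise_sd,
           locus_truth = de$truth$loci,
           gene_truth = de$truth$genes,
           layout_truth = layout$truth,
           cpg_truth = meth$truth,
           qpcr_truth = qpcr$truth),
      truth_path, auto_unbox = TRUE, digits = NA)
    out$paths <- c(layout$paths, de$paths, meth$paths,
                   qpcr = qpcr$path, truth = truth_path)
  }
  out
}
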