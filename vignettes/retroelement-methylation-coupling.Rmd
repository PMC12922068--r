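---
title: "Retroelement locus expression, consensus calling and methylation coupling"
author: "retromethyl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retroelement locus expression, consensus calling and methylation coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retromethyl)
```

## The problem

Individual genomic copies ("loci") of the HERV-K (HML-2) endogenous
retrovirus subgroup can be transcribed in tumors, and their activity may be
coupled to the expression of the genes they sit in or near, and to the
methylation state of nearby CpG sites. Quantifying locus-specific
retroelement expression from RNA-seq is difficult because the loci are
nearly identical in sequence, so several quantification tools are typically
run in parallel and only loci the tools agree on are carried forward.
`retromethyl` implements the downstream integration: cross-tool agreement
and consensus selection, locus–gene genomic association, CpG
methylation–expression coupling, and ΔΔCt qPCR summarization. Upstream
steps — read alignment, per-tool quantification, differential-expression
and differential-methylation model fitting, subtype classification — are
out of scope; the package consumes their tabular outputs.

## Data model and coordinate conventions

All features live in 1-based, fully closed coordinates (the Ensembl GTF
convention). BED input is 0-based half-open and converted at the boundary
(`start + 1`, `end`), and converted back on export, so round trips are
lossless. A gene's TSS is its `start` on the plus strand and its `end` on
the minus strand. Interval joins are delegated to
`GenomicRanges::findOverlaps()`; every join in the package is checked
against a brute-force all-pairs scan in the test suite.

Two details deserve attention:

* **Distance.** For 50-kb flank association, distance is the number of
  bases strictly between the two inclusive intervals (a locus ending at
  2000 and a gene starting at 52000 are 49,999 bp apart). Adjacent,
  non-overlapping intervals have distance 0 but remain "nearby", never
  "intragenic". For CpG pairing, distance is the offset beyond the partner
  boundary and the pairing test is *position within
  [start − window, end + window]* — so a site 3001 bp beyond a gene end is
  excluded at the default 3000-bp window.
* **Strand.** Overlap and proximity ignore strand; strand agreement is
  recorded as an attribute because antisense-embedded loci are a real and
  reported configuration.

## Consensus calling and agreement

Calls are categorized per tool as *up* (padj < alpha and log2FC ≥ lfc_min),
*down* (log2FC ≤ −lfc_min), else *ns*; the fold-change bound is inclusive,
the significance bound strict, and a missing adjusted p-value is *ns*
(never imputed). Cohen's kappa is the unweighted multi-category statistic
over the 3×3 confusion matrix of the features quantified by both tools;
features seen by only one tool are excluded rather than treated as *ns*,
which would inflate agreement. When both raters are constant and identical,
chance agreement is 1 and kappa is reported as 1 with a `degenerate` flag.

Two selection policies are implemented because both appear in practice:

* `all_significant_two_lfc` (default): padj < 0.05 in **all** tools and
  |log2FC| ≥ 1 in at least two;
* `anchor_plus_one`: the full threshold in a designated anchor tool
  (typically the most locus-aware one) and in at least one other.

A locus whose significant calls disagree in sign is excluded and logged,
not majority-voted; conflicting-direction consensus loci are not a
meaningful biological category.

## Methylation–expression coupling

CpG–gene pairs use a ±3000 bp window around the gene boundaries (promoters
lie within ±2000–3000 bp of the TSS); CpG–locus pairs use 10,000 bp.
Filtering keeps pairs with |methylation log2FC| > 0.1 and
|expression log2FC| > 1, each significant below 0.05. All fold-change
inequalities here are **strict** — a methylation effect of exactly 0.1 is
excluded — which intentionally differs from the inclusive "≥ 1" used for DE
calling; both conventions are kept as written in their respective stages.
The significance column defaults to the adjusted p-value for both sides and
can be toggled to raw p-values (`filter_config(use_adjusted_* = FALSE)`),
since reasonable analyses have used either. Filtering is idempotent, and
CpG–locus pairs can additionally be restricted to the consensus locus set.

Coupling is summarized two ways:

* **Spearman's rho** between the pair's methylation log2FC (X1) and the
  partner's expression log2FC (Y), chosen for small samples and non-linear
  monotone relations. Ties get midranks; the p-value is exact for n ≤ 10
  (without ties) and uses the t-approximation otherwise. A CpG pairing with
  k partners contributes k pairs, so pair counts can exceed unique-site
  counts; both are reported.
* **Interaction OLS.** For locus pairs,
  `Y = b0 + b1 X1 + b2 X2 + b3 X1 X2 + e` with X2 = 1 when the CpG and the
  locus share a strand; for gene pairs the promoter indicator X3 (TSS200
  membership from the manifest, *not* geometry) adds `b3 X3 + b5 X1 X3`.
  Errors are assumed independent Normal; the fit is plain unweighted least
  squares with no robust errors. If any design column has zero variance, or
  the design is rank-deficient, the model is **not applicable** and the
  reason is reported — this reproduces the situation where every pair of a
  subtype lies on one strand, or no CpG is in a promoter, and a coefficient
  table would be meaningless. For applicable gene fits the result notes
  whether the promoter interaction flips the methylation slope
  (`sign(b1) != sign(b1 + b5)`), the configuration of interest when
  promoter methylation represses while gene-body methylation tracks
  expression.

Illumina methylation probes carry no meaningful strand for this purpose;
when the manifest supplies no strand, the CpG is treated as "+"-strand and
the pair is flagged `strand_low_confidence`. This is the largest single
modeling assumption in the package and is surfaced in every pair table.

## qPCR summarization

ΔCt = Ct(target) − Ct(reference); ΔΔCt = ΔCt(tumor) − ΔCt(normal) per
patient; fold change 2^−ΔΔCt. Cohort summaries report the mean ± sample SD
(n − 1; the field norm when "M ± SD" is unqualified) of ΔΔCt, and *both*
fold-change conventions — the mean of per-patient fold changes and
2^−mean(ΔΔCt) — because they differ by Jensen's inequality (2^−x is convex,
so mean fc ≥ 2^−mean ΔΔCt always; this is property-tested). Technical
replicates are averaged per patient, tissue and target before ΔCt. A
single-pair cohort reports SD as missing. Primer-efficiency correction
(Pfaffl) is out of scope.

## The synthetic study

Because the motivating data are patient-level and not publicly deposited,
the package ships a generator that emulates every input class with known
ground truth. Its defaults are fixed study conditions, not tuning knobs:

* **Layout** — one 60-Mb synthetic chromosome, 120 non-overlapping genes,
  100 loci of 0.5–9 kb: 40% placed strictly inside a gene, 30% within
  1–45 kb of one, the rest isolated (> 50 kb from every gene), with
  intergenic gaps wide enough that every intended relation is unambiguous.
  Locus strands match their partner gene's with probability 0.5.
* **DE tables** — 30% of features truly differentially expressed; 60% of
  those form a "core" with |log2FC| in [1.5, 3]. Three pseudo-tools observe
  the true effect plus independent Normal noise whose SD is solved so the
  analytic inter-tool Pearson correlation
  Var(true)/(Var(true) + E Var(noise)) equals 0.9, matching the reported
  high cross-tool concordance (r > 0.88, kappa 0.92–0.96). Core loci are
  observed with bounded error (|noise| < 0.5, truncated Normal — the exact
  truncated variance enters the analytic solve) and are always called
  significant, so the core subset is a constructed recovery floor for
  closed-loop consensus tests; other true positives are called at per-tool
  sensitivity 0.9. P-values otherwise follow the z-test implied by the
  noise model, BH-adjusted.
* **Methylation** — 800 CpGs, half placed within 8 kb of loci and half on
  locus-hosting genes (promoter sites in the strand-aware TSS200 zone,
  200 bp upstream of the TSS), mirroring an analysis restricted to
  retroelement-containing genes. Coupled CpGs (80%) get a methylation
  log2FC consistent with their partner's true expression log2FC under the
  forward model — obtained by inverting the model and adding noise — with
  default coefficients b1 = −0.6 for loci (the inverse
  methylation–expression relationship) and b1 = +0.4, b5 = −0.9 for genes
  (positive gene-body coupling with a promoter sign flip).
* **qPCR** — 20 paired patients (a plausible validation-cohort size; the
  motivating cohort size is not published), true ΔΔCt of −0.92 ± 1.16
  (*env*) and −0.52 ± 1.30 (*gag*).

Everything is deterministic under the configured seed: identical
configurations produce byte-identical files, and the full pipeline is a
pure function of inputs and configuration (reruns are hash-identical).

What the generator does **not** emulate: realistic p-value/effect joint
distributions from count models, correlated CpGs in islands, multi-mapping
ambiguity between homologous loci (tool noise is independent Normal,
whereas real tools share systematic biases), copy-number effects, or
chromosome-scale structure beyond one synthetic chromosome (a
multi-chromosome layout only exercises the chromosome-matching code
paths). Passing the closed-loop tests therefore demonstrates correctness of
the integration logic under the stated model, not robustness to every
pathology of real tumor data.

A caveat worth knowing: in the file-level study the partner's expression
log2FC is constant across the CpGs of one partner, so the gene-side
regression is identified mainly by between-gene variation. With few unique
differentially expressed host genes in a draw, its coefficient estimates
are unstable and the design occasionally degenerates (all pairs on one
strand) — faithfully reproducing the small-subtype behaviour of real
studies. Exact estimator checks therefore use `simulate_pairs()`, which
draws the design per pair directly from the forward model.

## Numerical choices and problem sizes

* Kappa, consensus and filtering are exact set logic; no tolerances.
* OLS goes through `stats::lm` (QR); tests require agreement with a
  normal-equations solve to 1e-10 and noise-free recovery to 1e-8.
* Spearman ties use midranks (`stats::cor.test`); monotone-transform
  invariance is tested to 1e-12.
* Pair tables and link tables are sorted by id, so results are invariant
  under input row order.
* Test-suite problem sizes: 100 random layouts up to 500 × 500 features
  for the join oracles; 20 seeds × 200 loci for the consensus oracle; 200
  replicates at n = 300–400 for regression recovery (mean estimate within
  2 standard errors of the mean, from a single RNG stream); 20 seeds ×
  2000 loci for the concordance target (measured r within ±0.03 of the
  analytic 0.9). The whole suite runs in about a minute.

## Limitations

* The CpG strand convention (probes as "+"-strand) makes X2 a
  partner-strand indicator whenever the manifest is unstranded; treat
  strand-interaction coefficients accordingly.
* The consensus direction rule requires unanimity among significant tools;
  majority-direction variants are not offered.
* Sensitivity analysis of the regressions (omitted-variable robustness) and
  enrichment analyses are out of scope.
* The pipeline treats subtype labels as given; it performs no
  classification.
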