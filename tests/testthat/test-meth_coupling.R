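make_pairs <- function(X1, Y, X2 = NULL, X3 = NULL, kind = "cpg_locus") {
  n <- length(X1)
  d <- data.frame(pair_kind = kind,
                  cpg_id = sprintf("cg%04d", seq_len(n)),
                  partner_id = sprintf("P%04d", seq_len(n)),
                  X1 = X1, X2 = if (is.null(X2)) rep(0:1, length.out = n) else X2,
                  Y = Y, distance_bp = 0L,
                  meth_pvalue = 1e-5, meth_padj = 1e-4,
                  expr_pvalue = 1e-5, expr_padj = 1e-4,
                  stringsAsFactors = FALSE)
  if (!is.null(X3)) d$X3 <- X3
  d
}

test_that("promoter beta aggregation equals a group-by mean", {
  sites <- random_sites(4)
  sites$beta_tumor <- c(0.2, 0.4, 0.7, 0.9)
  sites$promoter_of <- I(list(c("G1"), c("G1"), c("G2"), character(0)))
  agg <- aggregate_promoter_beta(sites)
  expect_equal(agg$gene_id, c("G1", "G2"))
  expect_equal(agg$mean_beta, c(0.3, 0.7))
  expect_equal(agg$n_sites, c(2L, 1L))

  set.seed(17)
  sites2 <- random_sites(60)
  genes <- sprintf("G%02d", 1:20)
  sites2$beta_tumor <- runif(60)
  sites2$promoter_of <- I(lapply(1:60, function(i) sample(genes, sample(0:3, 1))))
  agg2 <- aggregate_promoter_beta(sites2)
  long <- data.frame(gene = unlist(sites2$promoter_of),
                     beta = rep(sites2$beta_tumor, lengths(sites2$promoter_of)))
  oracle <- tapply(long$beta, long$gene, mean)
  expect_equal(agg2$mean_beta, as.numeric(oracle[agg2$gene_id]))
})

test_that("CpG pairing respects the boundary window exactly", {
  genes <- genomic_features("G1", "gene", "chr1", 1000, 2000, "+")
  sites <- random_sites(3)
  sites$position <- c(900L, 5000L, 5001L)
  p <- pair_cpg_gene(sites, genes, window = 3000)
  expect_equal(p$cpg_id, c("cg00001", "cg00002"))  # 5001 is 3001 bp out
  expect_equal(p$distance_bp, c(100L, 3000L))

  loci <- genomic_features("L1", "locus", "chr1", 1000, 2000, "+")
  sites$position <- c(1500L, 12000L, 12001L)
  q <- pair_cpg_locus(sites, loci, window = 10000)
  expect_equal(q$cpg_id, c("cg00001", "cg00002"))
  expect_equal(q$distance_bp, c(0L, 10000L))
})

test_that("pairing matches the brute-force scan on random layouts", {
  set.seed(404)
  for (rep in 1:25) {
    sites <- random_sites(sample(20:100, 1), max_pos = 2e5)
    feats <- random_features(sample(10:60, 1), "gene", max_pos = 2e5)
    window <- sample(c(3000L, 10000L), 1)
    got <- pair_cpg_gene(sites, feats, window)
    expect_equal(got[c("cpg_id", "partner_id", "distance_bp")],
                 brute_force_pairs(sites, feats, window))
  }
})

test_that("X2 and X3 derive from strand and manifest promoter membership", {
  genes <- genomic_features(c("Gp", "Gm"), "gene", "chr1",
                            c(1000, 4000), c(2000, 5000), c("+", "-"))
  sites <- random_sites(1)
  sites$position <- 3000L
  sites$promoter_of <- I(list("Gm"))
  p <- pair_cpg_gene(sites, genes, window = 3000)
  p <- p[order(p$partner_id), ]
  expect_equal(p$partner_id, c("Gm", "Gp"))
  expect_equal(p$X2, c(0L, 1L))  # probe treated as '+'
  expect_equal(p$X3, c(1L, 0L))  # manifest flag, not geometry
})

test_that("filtering applies strict thresholds and is idempotent", {
  pairs <- make_pairs(X1 = c(0.1, -0.5, 0.5, 0.5, 0.5),
                      Y = c(2, 2, 1.0, -2, 2))
  pairs$meth_padj <- c(1e-4, 0.01, 1e-4, 1e-4, 0.06)
  de <- data.frame(feature_id = pairs$partner_id, log2fc = pairs$Y,
                   pvalue = 1e-4, padj = 1e-3)
  f <- filter_pairs(pairs, de)
  # row1: X1 == 0.1 dropped (strict); row3: |Y| == 1 dropped (strict);
  # row5: meth padj 0.06 dropped
  expect_equal(f$cpg_id, c("cg0002", "cg0004"))
  expect_equal(filter_pairs(f, de)[names(f)], f[names(f)])
})

test_that("a consensus set restricts locus-pair partners", {
  pairs <- make_pairs(X1 = rep(0.5, 4), Y = rep(2, 4))
  de <- data.frame(feature_id = pairs$partner_id, log2fc = 2,
                   pvalue = 1e-4, padj = 1e-3)
  f <- filter_pairs(pairs, de, consensus = pairs$partner_id[c(1, 3)])
  expect_equal(f$partner_id, pairs$partner_id[c(1, 3)])
})

test_that("pairs without a partner DE record are dropped and counted", {
  pairs <- make_pairs(X1 = rep(0.5, 3), Y = rep(NA_real_, 3))
  de <- data.frame(feature_id = pairs$partner_id[1], log2fc = 2,
                   pvalue = 1e-4, padj = 1e-3)
  f <- filter_pairs(pairs, de)
  expect_equal(nrow(f), 1L)
  expect_equal(attr(f, "n_no_de"), 2L)
})

test_that("toggling raw p-values changes which significance column gates", {
  pairs <- make_pairs(X1 = 0.5, Y = 2)
  pairs$meth_pvalue <- 0.01
  pairs$meth_padj <- 0.2
  de <- data.frame(feature_id = pairs$partner_id, log2fc = 2,
                   pvalue = 1e-4, padj = 1e-3)
  expect_equal(nrow(filter_pairs(pairs, de)), 0L)
  cfg <- filter_config(use_adjusted_meth_p = FALSE)
  expect_equal(nrow(filter_pairs(pairs, de, cfg)), 1L)
})

test_that("spearman coupling hits the monotone extremes and counts entities", {
  x <- c(0.3, -0.2, 0.8, 0.5, -0.6)
  up <- make_pairs(X1 = x, Y = exp(x))
  expect_equal(spearman_coupling(up)$rho, 1)
  down <- make_pairs(X1 = x, Y = -x)
  expect_equal(spearman_coupling(down)$rho, -1)
  shared <- make_pairs(X1 = c(x, x), Y = c(exp(x), -x))
  shared$cpg_id <- rep(sprintf("cg%d", 1:5), 2)  # each CpG pairs twice
  s <- spearman_coupling(shared)
  expect_equal(s$n_pairs, 10L)
  expect_equal(s$n_unique_cpgs, 5L)
  expect_true(s$n_unique_cpgs <= s$n_pairs)
})

test_that("spearman rho is invariant under strictly monotone transforms", {
  set.seed(55)
  for (rep in 1:20) {
    pairs <- make_pairs(X1 = rnorm(40), Y = rnorm(40))
    base <- spearman_coupling(pairs)$rho
    tx <- sample(list(function(v) v^3, function(v) exp(v),
                      function(v) 5 * v + 2, function(v) atan(v)), 2)
    warped <- pairs
    warped$X1 <- tx[[1]](warped$X1)
    warped$Y <- tx[[2]](warped$Y)
    expect_equal(spearman_coupling(warped)$rho, base, tolerance = 1e-12)
  }
})

test_that("constant inputs make the correlation undefined, not wrong", {
  pairs <- make_pairs(X1 = rep(0.5, 5), Y = rnorm(5))
  s <- spearman_coupling(pairs)
  expect_false(s$defined)
  expect_true(is.na(s$rho))
  expect_error(spearman_coupling(make_pairs(0.1, 1)), "at least 3")
})

test_that("OLS estimates equal the normal-equations oracle", {
  set.seed(66)
  for (rep in 1:20) {
    n <- sample(20:200, 1)
    pairs <- simulate_pairs(n, c(beta0 = 0.5, beta1 = -0.7, beta2 = 0.3,
                                 beta3 = 0.4), noise_sd = 0.5)
    res <- fit_locus_model(pairs)
    expect_true(res$applicable)
    X <- cbind(1, pairs$X1, pairs$X2, pairs$X1 * pairs$X2)
    expect_equal(res$coefficients$estimate,
                 unname(normal_equations_ols(X, pairs$Y)), tolerance = 1e-10)
  }
})

test_that("noise-free data are recovered exactly by both models", {
  pairs <- simulate_pairs(100, c(beta0 = 2, beta1 = -0.5, beta2 = 1,
                                 beta3 = 0.25), noise_sd = 0, seed = 1)
  res <- suppressWarnings(fit_locus_model(pairs))  # lm flags the perfect fit
  expect_equal(res$coefficients$estimate, c(2, -0.5, 1, 0.25),
               tolerance = 1e-8)
  expect_lt(res$residual_sd, 1e-8)

  gp <- simulate_pairs(200, c(beta0 = 1, beta1 = 0.4, beta2 = -0.2,
                              beta3 = 0.3, beta4 = 0.1, beta5 = -0.9),
                       noise_sd = 0, kind = "gene", seed = 2)
  resg <- suppressWarnings(fit_gene_model(gp))
  expect_equal(resg$coefficients$estimate, c(1, 0.4, -0.2, 0.3, 0.1, -0.9),
               tolerance = 1e-8)
  expect_true(resg$promoter_sign_flip)
})

test_that("degenerate designs are reported as not applicable with a reason", {
  same_strand <- simulate_pairs(50, c(beta1 = -0.5), seed = 3,
                                same_strand_frac = 1)
  res <- fit_locus_model(same_strand)
  expect_false(res$applicable)
  expect_match(res$inapplicability_reason, "strand indicator")
  expect_null(res$coefficients)

  no_promoter <- simulate_pairs(50, c(beta1 = 0.4), kind = "gene", seed = 4,
                                promoter_frac = 0)
  resg <- fit_gene_model(no_promoter)
  expect_false(resg$applicable)
  expect_match(resg$inapplicability_reason, "promoter")

  tiny <- simulate_pairs(4, c(beta1 = 1), seed = 5)
  expect_false(fit_locus_model(tiny)$applicable)
})

test_that("collinear designs are caught as rank-deficient", {
  pairs <- simulate_pairs(50, c(beta1 = -0.5), seed = 6)
  pairs$X2 <- as.integer(pairs$X1 > 0)  # X1:X2 collinear-ish is fine; force exact
  pairs$X1 <- pairs$X2 * 2              # X1 = 2 * X2 exactly
  res <- fit_locus_model(pairs)
  expect_false(res$applicable)
})
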