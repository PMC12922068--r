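test_that("categorization applies inclusive fold-change and strict alpha bounds", {
  expect_equal(as.character(categorize(2.3, 0.001)), "up")
  expect_equal(as.character(categorize(-1.0, 0.04)), "down")  # |lfc| == 1 counts
  expect_equal(as.character(categorize(1.0, 0.05)), "ns")     # padj == alpha fails
  expect_equal(as.character(categorize(0.9, 0.001)), "ns")
  expect_equal(as.character(categorize(3.0, NA)), "ns")       # missing padj
})

test_that("kappa matches the hand-evaluated 3x3 confusion example", {
  a <- data.frame(feature_id = 1:4, category = c("up", "up", "down", "ns"))
  b <- data.frame(feature_id = 1:4, category = c("up", "down", "down", "ns"))
  k <- cohen_kappa(a, b)
  expect_equal(k$p0, 0.75)
  expect_equal(k$pe, 0.3125)
  expect_equal(k$kappa, (0.75 - 0.3125) / (1 - 0.3125))
})

test_that("kappa equals the naive double-loop oracle on random call sets", {
  set.seed(101)
  for (rep in 1:100) {
    n <- sample(5:50, 1)
    a <- sample(c("up", "down", "ns"), n, replace = TRUE)
    b <- sample(c("up", "down", "ns"), n, replace = TRUE)
    if (all(a == b) && length(unique(a)) == 1) next  # degenerate, tested below
    got <- cohen_kappa(data.frame(feature_id = 1:n, category = a),
                       data.frame(feature_id = 1:n, category = b))
    want <- naive_kappa(a, b)
    expect_equal(got$kappa, want$kappa, tolerance = 1e-12)
    expect_equal(got$p0, want$p0, tolerance = 1e-12)
    expect_equal(got$pe, want$pe, tolerance = 1e-12)
    expect_true(got$kappa >= -1 && got$kappa <= 1)
  }
})

test_that("kappa of identical calls is 1 and constant raters are flagged", {
  a <- data.frame(feature_id = 1:6,
                  category = c("up", "ns", "down", "ns", "up", "ns"))
  self <- cohen_kappa(a, a)
  expect_equal(self$kappa, 1)
  expect_equal(self$p0, 1)
  const <- data.frame(feature_id = 1:5, category = rep("ns", 5))
  k <- cohen_kappa(const, const)
  expect_equal(k$kappa, 1)
  expect_true(k$degenerate)
})

test_that("kappa is invariant under feature order permutation", {
  set.seed(7)
  a <- data.frame(feature_id = 1:30,
                  category = sample(c("up", "down", "ns"), 30, TRUE))
  b <- data.frame(feature_id = 1:30,
                  category = sample(c("up", "down", "ns"), 30, TRUE))
  k1 <- cohen_kappa(a, b)
  perm <- sample(30)
  k2 <- cohen_kappa(a[perm, ], b[rev(perm), ])
  expect_equal(k1$kappa, k2$kappa)
})

test_that("kappa under label permutation is centred on zero", {
  set.seed(11)
  a <- sample(c("up", "down", "ns"), 200, replace = TRUE)
  ks <- replicate(500, {
    cohen_kappa(data.frame(feature_id = 1:200, category = a),
                data.frame(feature_id = 1:200, category = sample(a)))$kappa
  })
  expect_lt(abs(mean(ks)), 0.02)
})

test_that("pairwise agreement recovers perfect, flipped and noisy correlation", {
  set.seed(5)
  ids <- sprintf("L%03d", 1:200)
  base <- random_de(ids)
  tables <- list(toolA = base, toolB = base)
  ag <- pairwise_agreement(tables)
  expect_equal(ag$pearson_r, 1)
  expect_equal(ag$kappa, 1)
  expect_equal(ag$r_squared, 1)

  flipped <- base
  flipped$log2fc <- -base$log2fc
  ag2 <- pairwise_agreement(list(toolA = base, toolB = flipped))
  expect_equal(ag2$pearson_r, -1)

  # r matches the textbook two-pass formula
  noisy <- base
  noisy$log2fc <- base$log2fc + rnorm(200, 0, 0.5)
  ag3 <- pairwise_agreement(list(toolA = base, toolB = noisy))
  expect_equal(ag3$pearson_r, two_pass_pearson(base$log2fc, noisy$log2fc),
               tolerance = 1e-12)
})

test_that("pairs with fewer than 3 shared features are flagged not computable", {
  a <- random_de(c("L1", "L2"))
  b <- random_de(c("L1", "L9"))
  ag <- pairwise_agreement(list(toolA = a, toolB = b))
  expect_false(ag$computable)
  expect_true(is.na(ag$pearson_r))
})

test_that("consensus keeps a locus significant everywhere with 2/3 strong effects", {
  mk <- function(lfc, padj) data.frame(feature_id = "L1", log2fc = lfc,
                                       pvalue = padj, padj = padj,
                                       tool = "x", subtype = NA)
  tables <- list(toolA = mk(2.1, 1e-4), toolB = mk(1.5, 1e-4),
                 toolC = mk(0.8, 1e-4))
  sel <- consensus_select(tables, consensus_policy())
  expect_equal(sel$feature_id, "L1")
  expect_equal(sel$direction, "up")
})

test_that("direction conflicts are excluded and logged", {
  mk <- function(lfc) data.frame(feature_id = "L1", log2fc = lfc,
                                 pvalue = 1e-4, padj = 1e-4,
                                 tool = "x", subtype = NA)
  tables <- list(toolA = mk(2.0), toolB = mk(-1.5), toolC = mk(1.8))
  sel <- consensus_select(tables, consensus_policy())
  expect_equal(nrow(sel), 0L)
  expect_equal(attr(sel, "conflicts"), "L1")
})

test_that("both consensus policies match the row-by-row oracle", {
  policies <- list(
    consensus_policy("all_significant_two_lfc"),
    consensus_policy("anchor_plus_one", anchor_tool = "toolC")
  )
  for (seed in 1:8) {
    set.seed(seed)
    ids <- sprintf("L%03d", 1:200)
    tables <- list(toolA = random_de(ids), toolB = random_de(ids),
                   toolC = random_de(ids))
    # sprinkle in missing values
    for (t in names(tables)) {
      tables[[t]]$padj[sample(200, 10)] <- NA
    }
    for (policy in policies) {
      got <- consensus_select(tables, policy)
      expect_identical(got$feature_id, brute_force_consensus(tables, policy))
    }
  }
})

test_that("consensus selection is monotone in alpha and lfc_min", {
  set.seed(99)
  ids <- sprintf("L%03d", 1:150)
  tables <- list(toolA = random_de(ids), toolB = random_de(ids),
                 toolC = random_de(ids))
  base <- consensus_select(tables, consensus_policy(alpha = 0.05, lfc_min = 1))
  looser <- consensus_select(tables, consensus_policy(alpha = 0.2, lfc_min = 0.5))
  expect_true(all(base$feature_id %in% looser$feature_id))
})

test_that("an absent anchor tool is an error", {
  tables <- list(toolA = random_de("L1"), toolB = random_de("L1"))
  expect_error(
    consensus_select(tables, consensus_policy("anchor_plus_one",
                                              anchor_tool = "telescope")),
    "anchor tool")
  expect_error(consensus_policy("anchor_plus_one"), "anchor_tool")
})

test_that("venn regions partition the union", {
  r <- subtype_venn(list(A = c("x", "y"), B = c("y", "z")))
  expect_equal(r$A, "x")
  expect_equal(r$B, "z")
  expect_equal(r$`A&B`, "y")

  same <- subtype_venn(list(A = c("a", "b"), B = c("a", "b")))
  expect_equal(same$`A&B`, c("a", "b"))
  expect_length(same$A, 0)

  set.seed(3)
  sets <- lapply(1:4, function(i) sample(sprintf("f%03d", 1:300), 100))
  names(sets) <- paste0("CMS", 1:4)
  regions <- subtype_venn(sets)
  expect_equal(sum(lengths(regions)), length(unique(unlist(sets))))
  expect_length(regions, 2^4 - 1)
  all_ids <- unlist(regions)
  expect_equal(anyDuplicated(all_ids), 0L)  # pairwise disjoint
})
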