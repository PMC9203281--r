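test_that("BH adjustment equals the step-up definition", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_error(bhAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(31)
  for (i in 1:200) {
    p <- runif(sample(3:40, 1))
    q <- bhAdjust(p)
    expect_equal(q, bhBruteForce(p), tolerance = 1e-12)
    ## monotone non-decreasing in p within the family
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})

test_that("the NB Wald test is calibrated and antisymmetric", {
  expect_error(nbWaldDE(matrix(rpois(30, 10), 10, 3), c("a", "a", "b")),
               "2 replicates")
  ## label swap (factor level reversal) negates every log2FC exactly
  sim <- generateDECounts(nGenes = 300, n1 = 4, n2 = 4, dispersion = 0.1,
                          deFraction = 0.1, lfc = 2, seed = 5)
  cond <- sampleMeta(sim$expr)$condition
  de <- suppressMessages(nbWaldDE(sim$expr, cond))
  deSwap <- suppressMessages(
    nbWaldDE(sim$expr, factor(cond, levels = c("B", "A"))))
  expect_equal(de$log2FC, -deSwap$log2FC, tolerance = 1e-12)
  expect_equal(de$p_value, deSwap$p_value, tolerance = 1e-12)
  ## type-I error stays near nominal across a dispersion grid
  for (disp in c(0.05, 0.5)) {
    null <- generateDECounts(nGenes = 1500, n1 = 4, n2 = 4,
                             dispersion = disp, deFraction = 0, seed = 42)
    de0 <- suppressMessages(
      nbWaldDE(null$expr, sampleMeta(null$expr)$condition))
    rate <- mean(de0$p_value < 0.05)
    expect_gte(rate, 0.03); expect_lte(rate, 0.07)
  }
  ## planted 4-fold changes are recovered with high power
  pw <- generateDECounts(nGenes = 1000, n1 = 6, n2 = 6, dispersion = 0.05,
                         deFraction = 0.1, lfc = 2, seed = 7)
  dePw <- suppressMessages(nbWaldDE(pw$expr, sampleMeta(pw$expr)$condition))
  planted <- unlist(pw$truth@markerGenes)
  expect_gte(mean(dePw$q_value[match(planted, dePw$gene)] < 0.05), 0.9)
})

test_that("significance thresholding is strict and matches brute force", {
  de <- data.frame(gene = paste0("g", 1:6),
                   log2FC = c(2, 1, -1.5, 0.5, 3, -2),
                   q_value = c(0.01, 0.05, 0.02, 0.001, 0.06, 0.049))
  sg <- significantGenes(de, lfcMin = 1, qMax = 0.05)
  ## q exactly 0.05 is excluded (strict less-than)
  expect_false("g2" %in% sg$up)
  expect_setequal(sg$up, "g1")
  expect_setequal(sg$down, c("g3", "g6"))
  ## lfcMin 0 and qMax 1 keep everything
  all_ <- significantGenes(de, lfcMin = 0, qMax = 1.000001)
  expect_setequal(c(all_$up, all_$down), de$gene)
  ## brute-force filter on a random table
  set.seed(32)
  rde <- data.frame(gene = paste0("g", 1:200), log2FC = rnorm(200, sd = 2),
                    q_value = runif(200))
  sg2 <- significantGenes(rde)
  expect_setequal(sg2$up,
                  rde$gene[rde$q_value < 0.05 & rde$log2FC >= 1])
})

test_that("Fisher enrichment equals hypergeometric enumeration", {
  ## [[5,0],[0,5]]: only the table itself and its mirror are as extreme
  r <- fisherEnrichment(letters[1:5], letters[1:5], letters[1:10])
  expect_equal(r$p_value, 2 / 252, tolerance = 1e-12)
  ## empty overlap in the enrichment direction gives odds ratio 0
  r0 <- fisherEnrichment(letters[1:3], letters[4:6], letters[1:10])
  expect_equal(r0$odds_ratio, 0)
  expect_error(fisherEnrichment("a", "a", character(0)), "empty universe")
  ## full enumeration oracle on all tables with margins <= 8
  for (a in 0:8) for (b in 0:(8 - a)) for (cc in 0:(8 - a)) {
    dMax <- min(8 - b, 8 - cc)
    for (d in 0:dMax) {
      if (a + b + cc + d == 0) next
      u <- paste0("u", seq_len(a + b + cc + d))
      sel <- u[seq_len(a + b)]
      set <- c(u[seq_len(a)], u[a + b + seq_len(cc)])
      got <- fisherEnrichment(sel, set, u)$p_value
      expect_equal(got, min(1, fisherEnumerate(a, b, cc, d)),
                   tolerance = 1e-9)
    }
  }
})

test_that("Fisher p-values are conservative-or-uniform under the null", {
  set.seed(33)
  ps <- replicate(400, {
    u <- paste0("g", 1:80)
    sel <- sample(u, 20)
    set <- sample(u, 15)
    fisherEnrichment(sel, set, u)$p_value
  })
  ## exact test on a discrete table: P(p <= t) <= t
  for (t in c(0.01, 0.05, 0.1, 0.25))
    expect_lte(mean(ps <= t), t + 3 * sqrt(t * (1 - t) / 400))
})

test_that("permutation GSEA behaves on constructed and null sets", {
  set.seed(34)
  stats <- setNames(rnorm(400), paste0("g", 1:400))
  topSet <- names(sort(stats, decreasing = TRUE))[1:20]
  r <- gseaPermutation(stats, topSet, nPerm = 999, seed = 3)
  expect_gt(r$es, 0)
  expect_lte(r$p_value, 1 / 1000 + 1e-9)
  ## negating the ranking flips the enrichment-score sign
  rNeg <- gseaPermutation(-stats, topSet, nPerm = 99, seed = 3)
  expect_lt(rNeg$es, 0)
  expect_error(gseaPermutation(stats, paste0("x", 1:10), nPerm = 99),
               "disjoint")
  expect_error(gseaPermutation(stats, names(stats)[1:3], nPerm = 99),
               "fewer than")
  ## random sets on a random ranking give uniform p-values
  ps <- vapply(1:200, function(i) {
    gseaPermutation(stats, sample(names(stats), 25), nPerm = 199,
                    seed = i)$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})

test_that("the NB Wald stand-in tracks the reference NB implementation", {
  sim <- generateDECounts(nGenes = 400, n1 = 5, n2 = 5, dispersion = 0.1,
                          deFraction = 0.15, lfc = 2, seed = 9)
  cond <- sampleMeta(sim$expr)$condition
  ours <- suppressMessages(nbWaldDE(sim$expr, cond))
  dds <- suppressMessages(DESeq2::DESeqDataSetFromMatrix(
    countData = assay(sim$expr), colData = data.frame(condition = factor(cond)),
    design = ~condition))
  ref <- suppressMessages(DESeq2::results(suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))))
  common <- intersect(ours$gene, rownames(ref))
  lfcO <- ours$log2FC[match(common, ours$gene)]
  lfcR <- ref$log2FoldChange[match(common, rownames(ref))]
  ## the two routes agree on effect sizes and on the planted discoveries
  expect_gt(cor(lfcO, lfcR, use = "complete.obs"), 0.95)
  planted <- intersect(unlist(sim$truth@markerGenes), common)
  sigO <- ours$gene[ours$q_value < 0.05 & abs(ours$log2FC) >= 1]
  sigR <- rownames(ref)[!is.na(ref$padj) & ref$padj < 0.05 &
                          abs(ref$log2FoldChange) >= 1]
  expect_gt(mean(planted %in% sigO), 0.85)
  expect_gt(length(intersect(sigO, sigR)) /
              max(1, length(union(sigO, sigR))), 0.7)
})
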