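test_that("regional log2 fold change matches the pseudocount formula", {
  atl <- markerAtlas()
  ## a decoy gene expressed equally everywhere has fold change 0
  decoy <- setdiff(rownames(atl$expr), unlist(atl$truth@markerGenes))[1]
  fc <- regionalLog2FC(atl$expr, "cortex", 12,
                       excludedRegions = c("striatum", "amygdala"))
  expect_equal(unname(fc[decoy]), 0)
  ## a planted marker with noise-free offset 3 recovers 3 up to the
  ## pseudocount distortion, which stays below 0.2 at baseline >= 16
  mkr <- atl$truth@markerGenes$cortex
  expect_true(all(abs(fc[mkr] - 3) < 0.2))
  ## analytic recomputation with the pseudocount
  v <- assay(atl$expr); cd <- colData(atl$expr)
  w12 <- cd$week == 12
  ref <- sapply(c("thalamus", "cerebellum"), function(r)
    v[mkr[1], w12 & cd$region == r])
  self <- v[mkr[1], w12 & cd$region == "cortex"]
  expect_equal(unname(fc[mkr[1]]),
               log2((self + 1) / (mean(ref) + 1)))
  ## excluding the only high-expressing other region raises the fold change
  conf <- markerAtlas(confoundersPerRegion = 3)
  cg <- conf$truth@confounderGenes$striatum[1]
  fcA <- regionalLog2FC(conf$expr, "cortex", 12)
  fcB <- regionalLog2FC(conf$expr, "cortex", 12, excludedRegions = "striatum")
  expect_gt(fcB[cg], fcA[cg])
  expect_error(regionalLog2FC(atl$expr, "nowhere", 12), "absent")
})

test_that("marker derivation recovers planted sets and applies both filters", {
  atl <- markerAtlas(confoundersPerRegion = 5)
  mk <- deriveRegionalMarkers(atl$expr, weeks = 12:16)
  for (r in names(atl$truth@markerGenes))
    expect_setequal(geneSets(mk)[[r]], atl$truth@markerGenes[[r]])
  ## confounded decoys (also elevated in striatum/amygdala) are rejected
  expect_length(intersect(unlist(geneSets(mk)),
                          unlist(atl$truth@confounderGenes)), 0)

  ## all-weeks rule: a gene high in cortex only at week 12 is excluded
  atl2 <- markerAtlas()
  v <- assay(atl2$expr); cd <- colData(atl2$expr)
  decoy <- setdiff(rownames(atl2$expr), unlist(atl2$truth@markerGenes))[1]
  v[decoy, cd$region == "cortex" & cd$week == 12] <-
    v[decoy, cd$region == "cortex" & cd$week == 12] * 2^5
  be <- BulkExpressionSet(v, "RPKM", sampleMeta = as.data.frame(cd))
  mk2 <- deriveRegionalMarkers(be, weeks = 12:16)
  expect_false(decoy %in% unlist(geneSets(mk2)))

  ## planted offset below the threshold yields zero recovery
  low <- generateAtlas(200, c("cortex", "thalamus", "cerebellum"),
                       12:14, markersPerRegion = 5, markerLog2FC = 1.2,
                       noiseSD = 0, seed = 2)
  mkLow <- deriveRegionalMarkers(low$expr, weeks = 12:14,
                                 excludedRegions = character(0))
  expect_length(unlist(geneSets(mkLow)), 0)

  ## raising the threshold never grows a set (anti-monotone)
  mkHi <- deriveRegionalMarkers(atl$expr, weeks = 12:16, fcThreshold = 3.5)
  for (r in names(geneSets(mkHi)))
    expect_true(all(geneSets(mkHi)[[r]] %in% geneSets(mk)[[r]]))

  ## invariance to sample and gene order
  perm <- markerAtlas(confoundersPerRegion = 5)
  pe <- perm$expr[sample(nrow(perm$expr)), sample(ncol(perm$expr))]
  mkP <- deriveRegionalMarkers(pe, weeks = 12:16)
  for (r in names(geneSets(mk)))
    expect_setequal(geneSets(mkP)[[r]], geneSets(mk)[[r]])
})

test_that("protocol fold changes separate planted regional mixtures", {
  atl <- markerAtlas()
  org <- generateBulkOrganoids(atl$expr, c("Triple-i", "DualSMAD-i"), 4,
    list("Triple-i" = c(cortex = 1),
         "DualSMAD-i" = c(cerebellum = 1)),
    countNoise = FALSE, seed = 3)
  rpkm <- computeRPKM(org$expr)
  mk <- deriveRegionalMarkers(atl$expr, weeks = 12:16)
  fc <- protocolRegionalFoldChange(rpkm, mk)
  pg <- attr(fc, "perGene")[["Triple-i vs DualSMAD-i"]]
  ## all planted cortical markers are strictly up in the cortex-only protocol
  expect_true(all(pg$cortex > 0))
  expect_true(all(pg$cerebellum < 0))
  ## identical protocol means give all-zero fold changes
  same <- generateBulkOrganoids(atl$expr, c("A", "B"), 2,
    list(A = c(cortex = 1), B = c(cortex = 1)), countNoise = FALSE, seed = 4)
  fc0 <- protocolRegionalFoldChange(computeRPKM(same$expr), mk)
  expect_lt(max(abs(fc0$mean_lfc)), 1e-10)
  ## empty set skipped with a warning
  sets <- c(geneSets(mk), list(empty = character(0)))
  expect_warning(protocolRegionalFoldChange(rpkm, sets), "empty")
})

test_that("venn category z-scores follow the population-sd convention", {
  ## atlas with 12 markers per region so a regional set can split into two
  ## defined categories of >= 5 genes each
  atl <- generateAtlas(400,
    c("cortex", "thalamus", "cerebellum", "striatum", "amygdala"),
    12:16, markersPerRegion = 12, markerLog2FC = 3, noiseSD = 0, seed = 7,
    confoundRegions = c("striatum", "amygdala"))
  mk <- deriveRegionalMarkers(atl$expr, weeks = 12:16)
  cortexSet <- geneSets(mk)$cortex
  ## fabricate DE results: 6 cortex markers strongly up under protocol A in
  ## both of its comparisons, everything else null
  mkDE <- function(upGenes) {
    g <- rownames(atl$expr)
    data.frame(gene = g,
               log2FC = ifelse(g %in% upGenes, 3, 0),
               p_value = ifelse(g %in% upGenes, 1e-8, 0.9),
               q_value = ifelse(g %in% upGenes, 1e-6, 0.95))
  }
  de <- list("A_vs_B" = mkDE(cortexSet[1:6]),
             "A_vs_C" = mkDE(cortexSet[1:6]),
             "B_vs_C" = mkDE(character(0)))
  z <- vennCategoryZScore(de, mk, atl$expr, weeks = 12:16, minGenes = 5)
  cx <- z[z$set == "cortex", ]
  ## categories: A up (6 genes), B up (0), C up (0), shared (remaining 6)
  expect_equal(cx$n_genes[cx$category == "A_specific_up"], 6)
  expect_equal(cx$n_genes[cx$category == "shared"], 6)
  defined <- cx[!is.na(cx$zscore), ]
  ## a two-point z-score under the population sd is exactly +/- 1
  expect_equal(nrow(defined), 2)
  expect_setequal(round(abs(defined$zscore), 10), 1)
  expect_equal(mean(defined$zscore), 0)
  ## a category with < 5 genes carries no z-score
  de4 <- list("A_vs_B" = mkDE(cortexSet[1:4]),
              "A_vs_C" = mkDE(cortexSet[1:4]),
              "B_vs_C" = mkDE(character(0)))
  z4 <- vennCategoryZScore(de4, mk, atl$expr, weeks = 12:16, minGenes = 5)
  cx4 <- z4[z4$set == "cortex", ]
  expect_true(is.na(cx4$zscore[cx4$category == "A_specific_up"]))
  ## planted protocol-specific up genes outscore shared genes in the
  ## region's own samples when their expression is elevated there: boost the
  ## A-up genes in cortex samples and compare the two category z-scores
  v <- assay(atl$expr); cd <- colData(atl$expr)
  v[cortexSet[1:6], cd$region == "cortex"] <-
    v[cortexSet[1:6], cd$region == "cortex"] * 4
  be <- BulkExpressionSet(v, "RPKM", sampleMeta = as.data.frame(cd))
  z2 <- vennCategoryZScore(de, mk, be, weeks = 12:16, minGenes = 5)
  cx2 <- z2[z2$set == "cortex", ]
  expect_gt(cx2$zscore[cx2$category == "A_specific_up"],
            cx2$zscore[cx2$category == "shared"])
})
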