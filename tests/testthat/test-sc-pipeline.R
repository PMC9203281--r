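test_that("QC filtering applies exclusive-keep thresholds", {
  counts <- Matrix::Matrix(matrix(10, 4, 5), sparse = TRUE)
  rownames(counts) <- c("MT-1", "G1", "G2", "G3")
  colnames(counts) <- paste0("c", 1:5)
  counts["MT-1", 2] <- 100          # mito-heavy cell
  counts["G1", 3] <- 9990           # exactly 10000 total UMIs
  sce <- SingleCellExperiment(list(counts = counts),
    rowData = DataFrame(is_mito = c(TRUE, FALSE, FALSE, FALSE),
                        is_ribo = rep(FALSE, 4)))
  out <- qcFilter(sce, maxUMI = 10000, maxMitoFrac = 0.4)
  ## cell 2: 100/130 mito >= 40% -> removed; cell 3: >= 10000 UMIs -> removed
  expect_setequal(colnames(out), c("c1", "c4", "c5"))
  ## a 39.9% mito cell is kept (strictly-below rule)
  counts2 <- counts[, 1, drop = FALSE]
  counts2["MT-1", 1] <- 399; counts2["G1", 1] <- 401
  counts2["G2", 1] <- 100; counts2["G3", 1] <- 100
  sce2 <- SingleCellExperiment(list(counts = counts2), rowData = rowData(sce))
  expect_equal(ncol(qcFilter(sce2, maxMitoFrac = 0.4)), 1)
  expect_error(qcFilter(sce2, maxMitoFrac = 0.01), "every cell")
  ## brute-force oracle on a random dataset
  sim <- generateSCDataset(nCells = 200,
    celltypeSpec = list(nTypes = 3, nGenes = 150, markersPerType = 10),
    seed = 5)
  tot <- Matrix::colSums(assay(sim$sce, "counts"))
  mito <- Matrix::colSums(
    assay(sim$sce, "counts")[rowData(sim$sce)$is_mito, ]) / tot
  keep <- tot < 400 & mito < 0.1
  if (any(keep)) {
    out2 <- qcFilter(sim$sce, maxUMI = 400, maxMitoFrac = 0.1)
    expect_identical(colnames(out2), colnames(sim$sce)[keep])
  }
})

test_that("median normalization equalizes totals before log1p", {
  counts <- Matrix::Matrix(rbind(c(100, 150, 250), c(0, 50, 50)),
                           sparse = TRUE)
  dimnames(counts) <- list(c("G1", "G2"), c("c1", "c2", "c3"))
  sce <- SingleCellExperiment(list(counts = counts))
  out <- normalizeLog1p(sce)
  norm <- expm1(assay(out, "logcounts"))
  expect_equal(unname(colSums(norm)), rep(200, 3), tolerance = 1e-9)
  expect_equal(norm["G2", "c1"], 0)   # zeros stay zero
  counts0 <- counts; counts0[, 2] <- 0
  expect_error(normalizeLog1p(
    SingleCellExperiment(list(counts = counts0))), "c2")
})

test_that("HVG selection honors mean bounds and rewards bimodality", {
  n <- 120
  lg <- rbind(
    bimodal = log1p(c(rep(0, n / 2), rep(4, n / 2))),
    flat = log1p(rep(2, n)),
    constant = rep(0.5, n),
    high = log1p(rep(8, n)))
  lg <- rbind(lg, matrix(log1p(rpois(20 * n, 1)), 20, n,
                         dimnames = list(paste0("f", 1:20), NULL)))
  colnames(lg) <- paste0("c", seq_len(n))
  sce <- SingleCellExperiment(list(counts = expm1(lg), logcounts = lg))
  out <- suppressWarnings(selectHVG(sce, n = 5, meanLo = 0.005, meanHi = 3))
  hvg <- rownames(out)[rowData(out)$is_hvg]
  expect_true("bimodal" %in% hvg)       # bimodal beats flat at equal mean
  expect_false("flat" %in% hvg)
  expect_false("constant" %in% hvg)     # constant gene never variable
  expect_false("high" %in% hvg)         # mean above the upper bound
})

test_that("scaling clips only above and matches the z-score oracle", {
  set.seed(41)
  x <- matrix(rnorm(20 * 30, 2), 20, 30,
              dimnames = list(paste0("g", 1:20), paste0("c", 1:30)))
  out <- scaleClip(x, clip = 10)
  ref <- t(scale(t(x)))
  expect_equal(out, ref, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(unname(rowMeans(out)), rep(0, 20), tolerance = 1e-12)
  ## clipping applies above only
  y <- rbind(spike = c(rep(0, 29), 1000))
  sc <- scaleClip(rbind(y, x), clip = 2)
  expect_equal(max(sc), 2)
  expect_lt(min(sc), -2.5)
  ## zero-variance genes map to zero rows
  z <- scaleClip(rbind(const = rep(3, 30)), 10)
  expect_true(all(z == 0))
})

test_that("PCA embedding matches a full eigendecomposition up to sign", {
  set.seed(42)
  x <- matrix(rnorm(50 * 100), 50, 100,
              dimnames = list(paste0("g", 1:50), paste0("c", 1:100)))
  res <- pcaEmbed(x, nPcs = 10)
  expect_true(all(diff(res$varExplained) <= 1e-10))
  pr <- prcomp(t(x), center = TRUE)
  expect_equal(abs(unname(res$coords)), abs(unname(pr$x[, 1:10])),
               tolerance = 1e-8)
  ## exactly planar data: components beyond 2 carry no variance
  plane <- outer(rnorm(30), rnorm(40)) + outer(rnorm(30), rnorm(40))
  rp <- pcaEmbed(plane, nPcs = 5)
  expect_lt(max(rp$varExplained[3:5]), 1e-8)
  ## reconstruction error decreases monotonically in the number of PCs
  errs <- vapply(c(2, 5, 10, 20), function(k) {
    r <- pcaEmbed(x, nPcs = k)
    recon <- r$rotation %*% t(r$coords)
    sum((x - rowMeans(x) - recon)^2)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_error(pcaEmbed(x, nPcs = 60), "exceeds")
})

test_that("kNN graphs respect geometry and batch quotas", {
  set.seed(43)
  blobA <- matrix(rnorm(40 * 3), 40, 3)
  blobB <- matrix(rnorm(40 * 3, mean = 50), 40, 3)
  emb <- rbind(blobA, blobB)
  rownames(emb) <- paste0("c", 1:80)
  g <- knnGraph(emb, k = 5)
  ## far-separated blobs: no cross-blob edges in plain mode
  cross <- (g@edges$from <= 40) != (g@edges$to <= 40)
  expect_equal(sum(cross), 0)
  expect_true(all(g@edges$weight > 0))
  expect_true(all(g@edges$from != g@edges$to))
  ## batch-balanced: every cell gains neighbors in each batch
  batch <- rep(c("b1", "b2"), 40)
  gb <- knnGraph(emb, k = 6, mode = "batch_balanced", batch = batch)
  nbr <- neighborList(gb)
  for (i in seq_len(80))
    expect_setequal(unique(batch[nbr[[i]]]), c("b1", "b2"))
  ## neighbor sets match a brute-force distance sort
  emb2 <- matrix(rnorm(200 * 4), 200, 4,
                 dimnames = list(paste0("c", 1:200), NULL))
  k <- 7
  g2 <- knnGraph(emb2, k = k)
  nbr2 <- neighborList(g2)
  d <- as.matrix(dist(emb2)); diag(d) <- Inf
  for (i in sample(200, 25)) {
    ref <- order(d[i, ])[seq_len(k)]
    expect_true(all(ref %in% nbr2[[i]]))
  }
  expect_error(knnGraph(emb2, k = 200), "smaller")
  expect_error(knnGraph(emb2, k = 5, mode = "batch_balanced"), "batch")
})

test_that("Louvain clustering is exact on separable graphs and deterministic", {
  ## two disconnected 20-cliques resolve into exactly the two cliques
  emb <- rbind(matrix(rnorm(20 * 2, sd = 0.1), 20, 2),
               matrix(rnorm(20 * 2, mean = 100, sd = 0.1), 20, 2))
  rownames(emb) <- paste0("c", 1:40)
  g <- knnGraph(emb, k = 10)
  cl <- louvainCluster(g, resolution = 1, seed = 0)
  expect_equal(length(unique(cl)), 2)
  expect_equal(length(unique(cl[1:20])), 1)
  expect_equal(length(unique(cl[21:40])), 1)
  ## labels are size-ordered from 0
  expect_setequal(unique(cl), c(0L, 1L))
  ## resolution -> 0 on a connected graph collapses to one cluster
  embC <- matrix(rnorm(60 * 2), 60, 2)
  gC <- knnGraph(embC, k = 15)
  clC <- louvainCluster(gC, resolution = 1e-4, seed = 0)
  expect_lte(length(unique(clC)), 2)
  ## determinism under a fixed seed
  expect_identical(louvainCluster(g, 1, seed = 7),
                   louvainCluster(g, 1, seed = 7))
  ## planted five types recovered almost perfectly
  sim <- generateSCDataset(nCells = 500, celltypeSpec = list(nTypes = 5),
                           seed = 13)
  chain <- scChain(sim)
  expect_gte(mclust::adjustedRandIndex(chain$clusters, chain$truth), 0.9)
})

test_that("doublet scores are bounded, calibrated and selective", {
  expect_error(doubletScores(generateSCDataset(120,
    celltypeSpec = list(nTypes = 2, nGenes = 100, markersPerType = 10),
    seed = 1)$sce, threshold = 1.5), "threshold")
  ## homogeneous data without doublets: few false flags
  simH <- generateSCDataset(nCells = 300,
    celltypeSpec = list(nTypes = 2, nGenes = 200, markersPerType = 2,
                        baseMean = 1, markerMean = 1.2),
    doubletRate = 0, seed = 2)
  dsH <- doubletScores(simH$sce, expectedRate = 0.05, seed = 3)
  expect_true(all(dsH$score >= 0 & dsH$score <= 1))
  expect_lt(mean(dsH$is_doublet), 0.10)
  ## injected two-type doublets are separable
  sim <- generateSCDataset(nCells = 400, celltypeSpec = list(nTypes = 4),
                           doubletRate = 0.1, seed = 4)
  ds <- doubletScores(sim$sce, seed = 5)
  isD <- seq_len(400) %in% sim$truth@doubletIndices
  auc <- as.numeric(pROC::auc(pROC::roc(isD, ds$score, quiet = TRUE)))
  expect_gte(auc, 0.9)
})

test_that("the overestimated-variance t-test is conservative", {
  set.seed(44)
  x <- matrix(abs(rnorm(600 * 400, 1)), 600, 400,
              dimnames = list(paste0("g", 1:600), paste0("c", 1:400)))
  gr <- rep(c("focal", "rest"), c(100, 300))
  de <- ttestOverestimVar(x, gr, "focal", minFrac = 0)
  ## conservative null: empirical type-I below nominal
  expect_lte(mean(de$p_value < 0.05), 0.05)
  ## statistic magnitude never exceeds the standard Welch statistic
  welch <- vapply(1:50, function(i)
    abs(t.test(x[i, gr == "focal"], x[i, gr == "rest"])$statistic),
    numeric(1))
  expect_true(all(abs(de$stat[1:50]) <= welch + 1e-10))
  expect_error(ttestOverestimVar(x, gr, "nope"), "focal")
  ## planted markers detected with high power
  sim <- generateSCDataset(nCells = 400,
    celltypeSpec = list(nTypes = 2, nGenes = 300, markersPerType = 60),
    seed = 6)
  sce <- normalizeLog1p(sim$sce)
  lab <- sim$truth@celltypeLabels[colnames(sce)]
  deP <- ttestOverestimVar(assay(sce, "logcounts"), lab, "type1")
  mk <- rownames(sce)[1:60]
  hits <- deP$q_value[match(mk, deP$gene)] < 0.05 &
    deP$log2FC[match(mk, deP$gene)] > 0
  expect_gte(mean(hits, na.rm = TRUE), 0.8)
})

test_that("cluster annotation by correlation recovers matched types", {
  sim <- generateSCDataset(nCells = 300, celltypeSpec = list(nTypes = 4),
                           seed = 7)
  chain <- scChain(sim)
  lg <- assay(chain$sce, "logcounts")
  scaled <- scaleClip(lg, 10)
  ## identical datasets: unit diagonal, identity assignment
  ann <- clusterCorrelationAnnotate(scaled, chain$clusters, scaled,
                                    chain$clusters, chain$hvg)
  expect_equal(unname(diag(ann$correlation)), rep(1, nrow(ann$correlation)))
  expect_identical(unname(ann$assignment), names(ann$assignment))
  ## symmetry of the correlation
  expect_equal(ann$correlation, t(ann$correlation), tolerance = 1e-12)
  expect_error(clusterCorrelationAnnotate(scaled, chain$clusters, scaled,
                                          chain$clusters, "nope"), "empty")
})
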