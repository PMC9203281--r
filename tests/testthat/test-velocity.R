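test_that("velocity gene filtering applies the inclusive count threshold", {
  s <- rbind(low = c(rep(1, 29), 0),     # 29 spliced in total
             edge = rep(1, 30),          # exactly 30 in both layers
             high = rep(10, 30))
  u <- rbind(low = c(rep(10, 29), 10),   # plenty unspliced
             edge = rep(1, 30),
             high = rep(10, 30))
  colnames(s) <- colnames(u) <- paste0("c", 1:30)
  kept <- filterVelocityGenes(s, u, minCounts = 30)
  expect_false("low" %in% kept)            # below threshold on one layer
  expect_true("edge" %in% kept)            # boundary kept (>=)
  expect_true("high" %in% kept)
  ## brute-force oracle on random layers
  set.seed(51)
  rs <- matrix(rpois(50 * 20, 2), 50, 20,
               dimnames = list(paste0("g", 1:50), paste0("c", 1:20)))
  ru <- matrix(rpois(50 * 20, 2), 50, 20, dimnames = dimnames(rs))
  kept2 <- filterVelocityGenes(rs, ru, minCounts = 40)
  ref <- rownames(rs)[rowSums(rs) >= 40 & rowSums(ru) >= 40]
  expect_identical(kept2, ref)
  expect_error(filterVelocityGenes(rs, ru, minCounts = 1e6), "pass")
})

test_that("layer normalization is independent and matches the sc operation", {
  set.seed(52)
  s <- matrix(rpois(40 * 15, 5) + 1, 40, 15,
              dimnames = list(paste0("g", 1:40), paste0("c", 1:15)))
  u <- matrix(rpois(40 * 15, 3) + 1, 40, 15, dimnames = dimnames(s))
  lay <- normalizeLayers(s, u, log = FALSE)
  expect_equal(unname(colSums(lay$spliced)),
               rep(median(colSums(s)), 15), tolerance = 1e-9)
  expect_equal(unname(colSums(lay$unspliced)),
               rep(median(colSums(u)), 15), tolerance = 1e-9)
  ## scaling one layer leaves the other untouched
  lay2 <- normalizeLayers(s, 10 * u, log = FALSE)
  expect_equal(lay2$spliced, lay$spliced)
  ## cross-check against the single-cell normalization applied per layer
  sceS <- SingleCellExperiment(list(counts = Matrix::Matrix(s, sparse = TRUE)))
  refS <- assay(normalizeLog1p(sceS), "logcounts")
  lg <- normalizeLayers(s, u, log = TRUE)
  expect_equal(unname(lg$spliced), unname(as.matrix(refS)), tolerance = 1e-9)
  u0 <- u; u0[, 3] <- 0
  expect_error(normalizeLayers(s, u0), "c3")
})

test_that("moment smoothing averages neighborhoods including the focal cell", {
  set.seed(53)
  emb <- matrix(rnorm(30 * 3), 30, 3, dimnames = list(paste0("c", 1:30), NULL))
  g <- knnGraph(emb, k = 5)
  s <- matrix(rpois(10 * 30, 8), 10, 30,
              dimnames = list(paste0("g", 1:10), rownames(emb)))
  u <- matrix(rpois(10 * 30, 4), 10, 30, dimnames = dimnames(s))
  mom <- smoothMoments(list(spliced = s, unspliced = u), g)
  ## brute-force neighbor averaging oracle
  nbr <- neighborList(g)
  for (i in c(1, 12, 30)) {
    hood <- c(i, nbr[[i]])
    expect_equal(mom$Ms[i, ], rowMeans(s[, hood, drop = FALSE]))
    expect_equal(mom$Mu[i, ], rowMeans(u[, hood, drop = FALSE]))
  }
  ## smoothing reduces per-gene variance
  expect_true(all(apply(mom$Ms, 2, var) <= apply(s, 1, var) + 1e-9))
  ## identical cells are a fixed point
  sConst <- matrix(5, 10, 30, dimnames = dimnames(s))
  momC <- smoothMoments(list(spliced = sConst, unspliced = sConst), g)
  expect_true(all(momC$Ms == 5))
})

test_that("the steady-state fit is exact on constructed data", {
  set.seed(54)
  Ms <- matrix(rexp(200 * 8, 1 / 5), 200, 8,
               dimnames = list(paste0("c", 1:200), paste0("g", 1:8)))
  Mu <- 0.5 * Ms
  fit <- fitVelocity(Ms, Mu)
  expect_equal(unname(velocityGamma(fit)), rep(0.5, 8))
  expect_lt(max(abs(velocityValues(fit))), 1e-12)
  ## identity: velocity + gamma * Ms reconstructs Mu
  Mu2 <- Ms * rep(runif(8, 0.2, 2), each = 200) +
    matrix(rnorm(1600, sd = 0.1), 200, 8)
  fit2 <- suppressWarnings(fitVelocity(Ms, Mu2))
  recon <- velocityValues(fit2) + sweep(fit2@Ms, 2, velocityGamma(fit2), "*")
  expect_equal(recon, fit2@Mu, tolerance = 1e-10)
  ## all-zero spliced moments are dropped with a warning
  Ms0 <- Ms; Ms0[, 3] <- 0
  expect_warning(f0 <- fitVelocity(Ms0, Mu), "all-zero")
  expect_false("g3" %in% f0@genes)
})

test_that("planted kinetic regimes drive the velocity sign", {
  sim <- generateSCDataset(nCells = 400, celltypeSpec = list(nTypes = 4),
                           kineticsSpec = list(noiseSD = 0.05), seed = 55)
  sce <- sim$sce
  kin <- sim$truth@kinetics
  genes <- filterVelocityGenes(assay(sce, "spliced"), assay(sce, "unspliced"))
  lay <- list(spliced = as.matrix(assay(sce, "spliced")[genes, ]),
              unspliced = as.matrix(assay(sce, "unspliced")[genes, ]))
  emb <- pcaEmbed(scaleClip(assay(normalizeLog1p(sce), "logcounts"), 10),
                  nPcs = 20)$coords
  mom <- smoothMoments(lay, knnGraph(emb, k = 30))
  fit <- fitVelocity(mom$Ms, mom$Mu)
  kin <- kin[match(fit@genes, kin$gene), ]
  ## gamma recovery on steady-state genes
  slope <- kin$beta / kin$gammaTrue
  steady <- kin$regime == "steady"
  relErr <- abs(velocityGamma(fit)[steady] - slope[steady]) / slope[steady]
  expect_lt(max(relErr), 0.1)
  ## induction genes: positive mean velocity in the transient cells
  ind <- kin$gene[kin$regime == "induction"][1]
  labels <- sim$truth@celltypeLabels[colnames(sce)]
  transientCells <- names(labels)[labels == "type1"]
  expect_gt(mean(velocityValues(fit)[transientCells, ind]), 0)
})

test_that("per-type mean velocities summarize the transient arm", {
  sim <- generateSCDataset(nCells = 300,
    celltypeSpec = list(nTypes = 3, nGenes = 200, markersPerType = 20),
    kineticsSpec = list(noiseSD = 0.02, transientTypes = 1L), seed = 56)
  sce <- sim$sce
  genes <- filterVelocityGenes(assay(sce, "spliced"), assay(sce, "unspliced"))
  lay <- list(spliced = as.matrix(assay(sce, "spliced")[genes, ]),
              unspliced = as.matrix(assay(sce, "unspliced")[genes, ]))
  emb <- pcaEmbed(scaleClip(assay(normalizeLog1p(sce), "logcounts"), 10),
                  nPcs = 20)$coords
  mom <- smoothMoments(lay, knnGraph(emb, k = 30))
  fit <- fitVelocity(mom$Ms, mom$Mu)
  labels <- sim$truth@celltypeLabels[colnames(sce)]
  kin <- sim$truth@kinetics
  ## a baseline (non-marker) induction gene: "progenitor" type-1 cells on the
  ## induction arm exceed the mature steady-state types
  base <- intersect(kin$gene[kin$regime == "induction"],
                    grep("^G01[6-9]", fit@genes, value = TRUE))
  g <- base[1]
  mv <- celltypeMeanVelocity(fit, labels, g)
  expect_gt(mv[["type1"]], max(mv[c("type2", "type3")]))
  ## invariances and errors
  perm <- sample(length(labels))
  fitP <- fitVelocity(fit@Ms[perm, ], fit@Mu[perm, ])
  expect_equal(celltypeMeanVelocity(fitP, labels[perm], g), mv)
  expect_error(celltypeMeanVelocity(fit, labels, "absent"), "not retained")
  ## an all-zero velocity gene yields zero type means
  Ms1 <- fit@Ms[, 1:2]; Mu1 <- 0.7 * Ms1
  f0 <- fitVelocity(Ms1, Mu1)
  expect_equal(unname(celltypeMeanVelocity(f0, labels, colnames(Ms1)[1])),
               rep(0, 3), tolerance = 1e-12)
})
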