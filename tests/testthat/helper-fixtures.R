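library(SummarizedExperiment)
library(SingleCellExperiment)

## small deterministic bulk container
tinyBulk <- function(nGenes = 6, nSamples = 4, unit = "counts", seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(nGenes * nSamples, 50), nGenes, nSamples,
              dimnames = list(sprintf("g%02d", seq_len(nGenes)),
                              sprintf("s%02d", seq_len(nSamples))))
  BulkExpressionSet(m, unit = unit,
                    geneLengths = rep(1000, nGenes),
                    sampleMeta = data.frame(
                      condition = rep(c("A", "B"), length.out = nSamples)))
}

## standard synthetic atlas used by several marker tests
markerAtlas <- function(noiseSD = 0, seed = 7, confoundersPerRegion = 0,
                        nGenes = 400) {
  generateAtlas(nGenes,
                c("cortex", "thalamus", "cerebellum", "striatum", "amygdala"),
                12:16, markersPerRegion = 5, markerLog2FC = 3,
                noiseSD = noiseSD, seed = seed,
                confoundRegions = c("striatum", "amygdala"),
                confoundersPerRegion = confoundersPerRegion)
}

## run the standard single-cell chain up to clustering
scChain <- function(sim, nHvg = 300, nPcs = 30, k = 14, resolution = 1,
                    seed = 0) {
  sce <- qcFilter(sim$sce)
  sce <- normalizeLog1p(sce)
  sce <- suppressWarnings(selectHVG(sce, n = nHvg))
  hvg <- rownames(sce)[rowData(sce)$is_hvg]
  scaled <- scaleClip(assay(sce, "logcounts")[hvg, , drop = FALSE], 10)
  emb <- pcaEmbed(scaled, nPcs = min(nPcs, length(hvg) - 1L))$coords
  graph <- knnGraph(emb, k = k)
  clusters <- louvainCluster(graph, resolution = resolution, seed = seed)
  list(sce = sce, hvg = hvg, scaled = scaled, emb = emb, graph = graph,
       clusters = clusters,
       truth = sim$truth@celltypeLabels[colnames(sce)])
}

## majority planted type per cluster
clusterMajority <- function(clusters, truth) {
  vapply(split(truth[names(clusters)], clusters),
         function(x) names(sort(table(x), decreasing = TRUE))[1],
         character(1))
}

## brute-force BH step-up from the definition
bhBruteForce <- function(p) {
  m <- length(p)
  vapply(seq_len(m), function(i) {
    ge <- which(p >= p[i])
    min(1, min(vapply(ge, function(j) {
      rank_j <- sum(p <= p[j])
      m * p[j] / rank_j
    }, numeric(1))))
  }, numeric(1))
}

## two-sided Fisher p by full hypergeometric enumeration
fisherEnumerate <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  pObs <- dhyper(a, m, n, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}
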