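#' @include AllClasses.R utils.R io.R bulk-normalize.R region-markers.R
#' @include integration.R de.R enrichment.R sc-preprocess.R sc-graph.R
#' @include sc-doublets.R sc-de.R velocity.R synth-atlas.R synth-singlecell.R
NULL

#' Default pipeline configuration
#'
#' Returns the full nested configuration of a workflow with every stage
#' parameter at its reference default (kNN k = 14 for the day-50 style
#' clustering, 20 for integration, 30 for velocity smoothing; Louvain
#' resolution 4 / 2 for the two single-cell stages; scaling clip 10; 2000
#' highly variable genes with mean bounds (0.005, 1.5); doublet rate 0.05
#' with threshold 0.2; marker log2 fold-change threshold 2; DE thresholds
#' |log2FC| >= 1 with q < 0.05 and the 0.1/0.1 variant for the late-stage
#' comparison; 10000 top-variance genes and 3 correspondence axes).
#' Unknown keys in a user configuration are rejected.
#'
#' @param workflow \code{"bulk"} or \code{"sc"}.
#' @return nested list of parameters.
#' @export
defaultConfig <- function(workflow = c("bulk", "sc")) {
  workflow <- match.arg(workflow)
  if (workflow == "bulk") {
    regions <- c("cortex", "thalamus", "cerebellum", "hippocampus",
                 "subpallium", "striatum", "amygdala")
    list(
      workflow = "bulk",
      simulate = TRUE,
      seed = 1L,
      outdir = "bulk_run",
      atlas = list(path = NULL, nGenes = 3000, regions = regions,
                   weeks = 12:21, markersPerRegion = 10, markerLog2FC = 3,
                   noiseSD = 0.3,
                   confoundRegions = c("striatum", "amygdala"),
                   confoundersPerRegion = 10),
      organoids = list(path = NULL,
        protocols = c("Triple-i", "DualSMAD-i", "Inhibitor-free"),
        samplesPerProtocol = 8, depth = 2e6, dispersion = 0.1,
        mixtures = list(
          "Triple-i" = c(cortex = 0.80, thalamus = 0.05, cerebellum = 0.05,
                         hippocampus = 0.05, subpallium = 0.05),
          "DualSMAD-i" = c(cortex = 0.05, thalamus = 0.10, cerebellum = 0.70,
                           hippocampus = 0.10, subpallium = 0.05),
          "Inhibitor-free" = c(cortex = 0.20, thalamus = 0.20,
                               cerebellum = 0.20, hippocampus = 0.20,
                               subpallium = 0.20))),
      markers = list(weeks = 12:21, fcThreshold = 2,
                     confoundQuantifier = "any"),
      integration = list(nVarGenes = 10000, k = 3),
      de = list(lfcMin = 1, qMax = 0.05),
      venn = list(minGenes = 5)
    )
  } else {
    list(
      workflow = "sc",
      simulate = TRUE,
      seed = 1L,
      outdir = "sc_run",
      input = list(path = NULL),
      sim = list(nCells = 600, nTypes = 5, nGenes = 600, markersPerType = 40,
                 doubletRate = 0.05, kinetics = FALSE),
      qc = list(maxUMI = 10000, maxMitoFrac = 0.4, maxRiboFrac = NULL),
      hvg = list(n = 2000, meanLo = 0.005, meanHi = 1.5),
      scale = list(clip = 10),
      pca = list(nPcs = 50),
      neighbors = list(k = 14, mode = "plain"),
      cluster = list(resolution = 4),
      doublets = list(expectedRate = 0.05, threshold = 0.2),
      de = list(minFrac = 0.02, lfcMin = 1, qMax = 0.05),
      velocity = list(enabled = FALSE, minCounts = 30, k = 30)
    )
  }
}

#' Load and validate a pipeline configuration
#'
#' Merges a user configuration (list or YAML file path) over the defaults of
#' \code{\link{defaultConfig}}; any key absent from the defaults is rejected.
#'
#' @param config list, path to a YAML file, or NULL for pure defaults.
#' @param workflow \code{"bulk"} or \code{"sc"} (defaulted from the config's
#'   own \code{workflow} key when present).
#' @return validated nested list.
#' @export
loadConfig <- function(config = NULL, workflow = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- config %||% list()
  workflow <- workflow %||% config$workflow %||% "bulk"
  defaults <- defaultConfig(workflow)
  .checkKeys <- function(user, def, path = "") {
    bad <- setdiff(names(user), names(def))
    .stopIf(length(bad) > 0, "unknown configuration key(s): %s",
            paste0(path, bad, collapse = ", "))
    for (k in names(user))
      if (is.list(def[[k]]) && !is.null(names(def[[k]])) && is.list(user[[k]]))
        .checkKeys(user[[k]], def[[k]], paste0(path, k, "."))
  }
  ## list-valued leaves that accept arbitrary names
  freeKeys <- c("mixtures")
  scrub <- function(u) { u[setdiff(names(u), freeKeys)] }
  .checkKeys(scrub(config), defaults)
  utils::modifyList(defaults, config)
}

.writeManifest <- function(outdir, config, files, extra = list()) {
  files <- files[file.exists(files)]
  manifest <- c(list(
    config = config,
    ## the digest excludes the output location so that reruns of one
    ## configuration are comparable across directories
    config_md5 = .paramsDigest(config[setdiff(names(config), "outdir")]),
    files = lapply(stats::setNames(as.list(files), basename(files)),
                   function(f) unname(tools::md5sum(f)))
  ), extra)
  path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  path
}

#' Write correspondence-analysis coordinates as CSV
#'
#' Two CSVs (row and column coordinates) with the inertia decomposition in
#' comment header lines.
#'
#' @param ca a \linkS4class{CAResult}.
#' @param prefix output path prefix.
#' @return invisibly, the two paths.
#' @export
writeCAResult <- function(ca, prefix) {
  hdr <- c(sprintf("# total_inertia: %.10g", ca@totalInertia),
           sprintf("# axis_inertia_fractions: %s",
                   paste(sprintf("%.10g", ca@axisInertia), collapse = ",")))
  wr <- function(m, path) {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(hdr, con)
    utils::write.csv(data.frame(id = rownames(m), m, check.names = FALSE),
                     con, row.names = FALSE)
    path
  }
  p1 <- wr(ca@rowCoords, paste0(prefix, ".rows.csv"))
  p2 <- wr(ca@colCoords, paste0(prefix, ".columns.csv"))
  invisible(c(p1, p2))
}

#' Run the bulk regional-identity workflow
#'
#' Normalization, regional marker derivation, atlas integration by
#' batch-adjusted correspondence analysis, pairwise differential expression
#' between protocols, regional gene-set enrichment, and the Venn-category
#' z-score summary — on simulated data (\code{simulate: true}) or on user
#' matrices. All artifacts are written under \code{outdir} together with a
#' manifest of configuration and file checksums.
#'
#' @param config configuration (list / YAML path / NULL), see
#'   \code{\link{loadConfig}}.
#' @return invisibly, a list with the in-memory results (markers, DE tables,
#'   enrichment tables, venn z-scores, integration) and \code{manifest}.
#' @export
runBulkWorkflow <- function(config = NULL) {
  cfg <- loadConfig(config, "bulk")
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  if (isTRUE(cfg$simulate)) {
    a <- cfg$atlas
    atl <- generateAtlas(a$nGenes, a$regions, a$weeks, a$markersPerRegion,
                         a$markerLog2FC, a$noiseSD, seed = cfg$seed,
                         confoundRegions = a$confoundRegions,
                         confoundersPerRegion = a$confoundersPerRegion)
    atlas <- atl$expr
    o <- cfg$organoids
    mixtures <- lapply(o$mixtures, function(m) unlist(m))
    org <- generateBulkOrganoids(atlas, o$protocols, o$samplesPerProtocol,
                                 mixtures, depth = o$depth,
                                 dispersion = o$dispersion,
                                 seed = cfg$seed + 1L)
    organoidCounts <- org$expr
    writeTruth(atl$truth, file.path(cfg$outdir, "atlas_truth.json"))
    writeTruth(org$truth, file.path(cfg$outdir, "organoid_truth.json"))
  } else {
    .stopIf(is.null(cfg$atlas$path) || is.null(cfg$organoids$path),
            "missing inputs: atlas.path and organoids.path are required %s",
            "when simulate is false")
    atlas <- readExpressionTSV(cfg$atlas$path)
    organoidCounts <- readExpressionTSV(cfg$organoids$path)
  }

  ## normalization chain
  organoidRPKM <- equalSumNormalize(computeRPKM(organoidCounts))

  ## regional markers
  markers <- deriveRegionalMarkers(atlas, weeks = cfg$markers$weeks,
    fcThreshold = cfg$markers$fcThreshold,
    excludedRegions = cfg$atlas$confoundRegions,
    confoundQuantifier = cfg$markers$confoundQuantifier)
  gmtPath <- file.path(cfg$outdir, "regional_markers.gmt")
  writeGMT(markers, gmtPath)

  ## pairwise DE between protocols
  prot <- unique(colData(organoidCounts)$protocol)
  pairs <- utils::combn(prot, 2, simplify = FALSE)
  deList <- list()
  for (pr in pairs) {
    sel <- colData(organoidCounts)$protocol %in% pr
    cts <- assay(organoidCounts)[, sel, drop = FALSE]
    cond <- factor(colData(organoidCounts)$protocol[sel], levels = pr)
    de <- nbWaldDE(cts, as.character(cond))
    key <- paste0(pr[2], "_vs_", pr[1])
    deList[[key]] <- de
    utils::write.csv(de, file.path(cfg$outdir, paste0("de_", key, ".csv")),
                     row.names = FALSE)
  }

  ## per-protocol consistent up-genes and regional enrichment
  upByProtocol <- lapply(prot, function(p) {
    lists <- list()
    for (key in names(deList)) {
      pr <- strsplit(key, "_vs_", fixed = TRUE)[[1]]
      de <- deList[[key]]
      sg <- significantGenes(de, cfg$de$lfcMin, cfg$de$qMax)
      if (p == pr[1]) lists[[length(lists) + 1L]] <- sg$up
      else if (p == pr[2]) lists[[length(lists) + 1L]] <- sg$down
    }
    Reduce(intersect, lists)
  })
  names(upByProtocol) <- prot
  enrichment <- list()
  for (p in prot) {
    universe <- deList[[1]]$gene
    enr <- enrichGeneSets(upByProtocol[[p]], markers, universe)
    enrichment[[p]] <- enr
    utils::write.csv(enr,
      file.path(cfg$outdir, paste0("enrichment_", gsub("[^A-Za-z0-9]", "_", p),
                                   "_up.csv")), row.names = FALSE)
  }

  ## Venn category z-scores over the atlas window
  venn <- vennCategoryZScore(deList, markers, atlas,
                             weeks = cfg$markers$weeks,
                             minGenes = cfg$venn$minGenes,
                             lfcMin = cfg$de$lfcMin, qMax = cfg$de$qMax)
  utils::write.csv(venn, file.path(cfg$outdir, "venn_zscores.csv"),
                   row.names = FALSE)

  ## atlas integration by correspondence analysis
  integration <- integrateAtlasOrganoids(atlas, organoidRPKM,
    nVarGenes = cfg$integration$nVarGenes, k = cfg$integration$k)
  caPaths <- writeCAResult(integration$ca, file.path(cfg$outdir, "ca"))
  utils::write.csv(data.frame(sample = rownames(integration$sampleInfo),
                              integration$sampleInfo),
                   file.path(cfg$outdir, "ca.samples.csv"), row.names = FALSE)

  files <- c(gmtPath, caPaths, file.path(cfg$outdir, "ca.samples.csv"),
             file.path(cfg$outdir, "venn_zscores.csv"),
             file.path(cfg$outdir, paste0("de_", names(deList), ".csv")))
  manifest <- .writeManifest(cfg$outdir, cfg, files)
  invisible(list(config = cfg, markers = markers, de = deList,
                 upByProtocol = upByProtocol, enrichment = enrichment,
                 venn = venn, integration = integration,
                 manifest = manifest))
}

#' Run the single-cell identity (and optional velocity) workflow
#'
#' QC filtering, doublet scoring and removal, median-total normalization,
#' highly-variable-gene selection, scaling, PCA, kNN graph, Louvain
#' clustering, per-cluster differential expression, and — when
#' spliced/unspliced layers are present and enabled — deterministic
#' steady-state RNA velocity. Artifacts (cluster and doublet tables keyed by
#' barcode, per-cluster DE CSVs, velocity gamma CSV) are written under
#' \code{outdir} with a manifest.
#'
#' @param config configuration (list / YAML path / NULL), see
#'   \code{\link{loadConfig}}.
#' @return invisibly, a list with the filtered dataset, cluster labels,
#'   doublet table, DE tables, optional velocity result and the manifest
#'   path; on simulated data the manifest also records the adjusted Rand
#'   index against the planted cell types.
#' @export
runSCWorkflow <- function(config = NULL) {
  cfg <- loadConfig(config, "sc")
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  truth <- NULL
  if (isTRUE(cfg$simulate)) {
    ks <- if (isTRUE(cfg$sim$kinetics)) list() else NULL
    sim <- generateSCDataset(nCells = cfg$sim$nCells,
      celltypeSpec = list(nTypes = cfg$sim$nTypes, nGenes = cfg$sim$nGenes,
                          markersPerType = cfg$sim$markersPerType),
      doubletRate = cfg$sim$doubletRate, kineticsSpec = ks,
      seed = cfg$seed)
    sce <- sim$sce
    truth <- sim$truth
    writeTruth(truth, file.path(cfg$outdir, "truth.json"))
  } else {
    .stopIf(is.null(cfg$input$path), "missing inputs: input.path (MTX dir)")
    sce <- readTenX(cfg$input$path)
  }
  .stopIf(isTRUE(cfg$velocity$enabled) &&
            !all(c("spliced", "unspliced") %in%
                   SummarizedExperiment::assayNames(sce)),
          "velocity requested but spliced/unspliced layers are absent")

  nRaw <- ncol(sce)
  sce <- qcFilter(sce, maxUMI = cfg$qc$maxUMI,
                  maxMitoFrac = cfg$qc$maxMitoFrac,
                  maxRiboFrac = cfg$qc$maxRiboFrac)
  nQC <- ncol(sce)

  dbl <- doubletScores(sce, expectedRate = cfg$doublets$expectedRate,
                       threshold = cfg$doublets$threshold, seed = cfg$seed)
  utils::write.table(data.frame(barcode = rownames(dbl), dbl),
    file.path(cfg$outdir, "doublets.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  sceClean <- sce[, !dbl$is_doublet]
  nClean <- ncol(sceClean)

  sceClean <- normalizeLog1p(sceClean)
  sceClean <- selectHVG(sceClean, n = cfg$hvg$n, meanLo = cfg$hvg$meanLo,
                        meanHi = cfg$hvg$meanHi)
  hvg <- rownames(sceClean)[rowData(sceClean)$is_hvg]
  scaled <- scaleClip(assay(sceClean, "logcounts")[hvg, , drop = FALSE],
                      clip = cfg$scale$clip)
  nPcs <- min(cfg$pca$nPcs, nrow(scaled) - 1L, ncol(scaled) - 1L)
  emb <- pcaEmbed(scaled, nPcs = nPcs)$coords
  graph <- knnGraph(emb, k = cfg$neighbors$k, mode = cfg$neighbors$mode,
                    batch = if (cfg$neighbors$mode == "batch_balanced")
                      colData(sceClean)$batch else NULL)
  clusters <- louvainCluster(graph, resolution = cfg$cluster$resolution,
                             seed = cfg$seed)
  utils::write.table(data.frame(barcode = names(clusters),
                                cluster = clusters),
    file.path(cfg$outdir, "clusters.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  deTables <- list()
  lg <- assay(sceClean, "logcounts")
  for (cl in sort(unique(clusters))) {
    if (sum(clusters == cl) < 2) next
    de <- ttestOverestimVar(lg, clusters, cl, minFrac = cfg$de$minFrac)
    deTables[[as.character(cl)]] <- de
    utils::write.csv(de,
      file.path(cfg$outdir, sprintf("de_cluster%02d.csv", cl)),
      row.names = FALSE)
  }

  velocity <- NULL
  if (isTRUE(cfg$velocity$enabled)) {
    sp <- assay(sceClean, "spliced"); un <- assay(sceClean, "unspliced")
    genes <- filterVelocityGenes(sp, un, cfg$velocity$minCounts)
    lay <- normalizeLayers(sp[genes, , drop = FALSE],
                           un[genes, , drop = FALSE])
    vGraph <- knnGraph(emb, k = cfg$velocity$k)
    mom <- smoothMoments(lay, vGraph)
    velocity <- fitVelocity(mom$Ms, mom$Mu)
    utils::write.csv(data.frame(gene = velocity@genes,
                                gamma = velocity@gamma),
      file.path(cfg$outdir, "velocity_gamma.csv"), row.names = FALSE)
  }

  extra <- list(cells = list(raw = nRaw, after_qc = nQC,
                             after_doublet_removal = nClean,
                             doublets_flagged = nQC - nClean))
  if (!is.null(truth)) {
    labels <- truth@celltypeLabels[colnames(sceClean)]
    extra$ari_vs_truth <- mclust::adjustedRandIndex(clusters, labels)
  }
  files <- c(file.path(cfg$outdir, c("clusters.tsv", "doublets.tsv")),
             file.path(cfg$outdir,
                       sprintf("de_cluster%02d.csv",
                               as.integer(names(deTables)))))
  if (!is.null(velocity))
    files <- c(files, file.path(cfg$outdir, "velocity_gamma.csv"))
  manifest <- .writeManifest(cfg$outdir, cfg, files, extra)
  invisible(list(config = cfg, sce = sceClean, clusters = clusters,
                 doublets = dbl, de = deTables, velocity = velocity,
                 truth = truth, manifest = manifest))
}
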