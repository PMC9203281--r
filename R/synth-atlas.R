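#' @include AllClasses.R utils.R
NULL

#' Generate a synthetic developmental brain atlas
#'
#' Emulates the layout of a fetal brain expression atlas: one RPKM sample per
#' (region, week), a shared heavy-tailed lognormal baseline per gene, and
#' regional marker genes planted as an additive log2 offset in their region
#' across all weeks. Optional confound decoys are elevated both in a target
#' region and (more strongly) in a confound region such as striatum or
#' amygdala, so that a confound filter is required to reject them.
#'
#' Marker and confounder baselines are floored at \code{minMarkerBaseline}:
#' fold-change recovery with a pseudocount is only well defined away from the
#' pseudocount floor, and regional markers in real atlases are well-expressed
#' genes.
#'
#' @param nGenes total number of genes.
#' @param regions character vector of region names (markers are planted in
#'   every region not listed in \code{confoundRegions}).
#' @param weeks integer vector of developmental weeks (one sample per
#'   region/week).
#' @param markersPerRegion planted markers per (non-confound) region.
#' @param markerLog2FC additive log2 offset of a marker in its region.
#' @param noiseSD per-entry log2-scale Gaussian noise (0 = noise-free).
#' @param seed integer seed; the same seed reproduces the matrix bit for bit.
#' @param confoundRegions regions that receive no marker set of their own and
#'   host the confound decoys (e.g. \code{c("striatum", "amygdala")}).
#' @param confoundersPerRegion decoy genes planted per confound region; each
#'   decoy is elevated by \code{markerLog2FC} in a (cycled) target region and
#'   by \code{markerLog2FC + 2} in the confound region.
#' @param minMarkerBaseline baseline RPKM floor for planted genes.
#' @return list with elements \code{expr} (a \linkS4class{BulkExpressionSet},
#'   unit RPKM, with \code{region}/\code{week} sample annotations and gene
#'   lengths) and \code{truth} (a \linkS4class{SyntheticTruth}).
#' @examples
#' atl <- generateAtlas(200, c("cortex", "thalamus", "cerebellum"), 12:15,
#'                      markersPerRegion = 5, seed = 1)
#' atl$truth
#' @export
generateAtlas <- function(nGenes, regions, weeks, markersPerRegion = 10,
                          markerLog2FC = 3, noiseSD = 0, seed = 1,
                          confoundRegions = character(0),
                          confoundersPerRegion = 0,
                          minMarkerBaseline = 16) {
  .stopIf(nGenes <= 0 || length(regions) < 2 || length(weeks) < 2,
          "need positive gene count, >= 2 regions and >= 2 weeks")
  markerRegions <- setdiff(regions, confoundRegions)
  .stopIf(length(markerRegions) < 1, "no non-confound regions left")
  nMark <- markersPerRegion * length(markerRegions)
  nConf <- confoundersPerRegion * length(confoundRegions)
  .stopIf(nMark + nConf > nGenes,
          "markers + confounders (%d) exceed nGenes (%d)", nMark + nConf, nGenes)
  .withSeed(.deriveSeed(seed, 11L), {
    genes <- sprintf("g%05d", seq_len(nGenes))
    baseline <- stats::rlnorm(nGenes, meanlog = 1, sdlog = 1)
    names(baseline) <- genes
    lengths <- round(stats::runif(nGenes, 500, 8000))

    markerGenes <- list()
    idx <- 0L
    for (r in markerRegions) {
      markerGenes[[r]] <- genes[idx + seq_len(markersPerRegion)]
      idx <- idx + markersPerRegion
    }
    confounderGenes <- stats::setNames(
      rep(list(character(0)), length(confoundRegions)), confoundRegions)
    confTargets <- character(0)
    if (nConf > 0) {
      for (cr in confoundRegions) {
        confounderGenes[[cr]] <- genes[idx + seq_len(confoundersPerRegion)]
        idx <- idx + confoundersPerRegion
      }
      confTargets <- rep(markerRegions,
                         length.out = confoundersPerRegion)
    }
    planted <- c(unlist(markerGenes), unlist(confounderGenes))
    ## floor planted baselines away from the pseudocount regime, with a
    ## spread so planted genes do not share one identical baseline
    baseline[planted] <- pmax(baseline[planted],
      minMarkerBaseline * exp(stats::runif(length(planted), 0, 1)))

    ## log2 offset matrix genes x regions
    offset <- matrix(0, nGenes, length(regions),
                     dimnames = list(genes, regions))
    for (r in names(markerGenes)) offset[markerGenes[[r]], r] <- markerLog2FC
    for (cr in names(confounderGenes)) {
      cg <- confounderGenes[[cr]]
      if (!length(cg)) next
      offset[cg, cr] <- markerLog2FC + 2
      for (i in seq_along(cg)) offset[cg[i], confTargets[i]] <-
        pmax(offset[cg[i], confTargets[i]], markerLog2FC)
    }

    samples <- expand.grid(week = weeks, region = regions,
                           stringsAsFactors = FALSE)[, c("region", "week")]
    sampleIds <- sprintf("%s_wk%02d", samples$region, samples$week)
    expr <- matrix(0, nGenes, nrow(samples),
                   dimnames = list(genes, sampleIds))
    for (j in seq_len(nrow(samples))) {
      lfc <- offset[, samples$region[j]]
      noise <- if (noiseSD > 0) stats::rnorm(nGenes, 0, noiseSD) else 0
      expr[, j] <- baseline * 2^(lfc + noise)
    }
    be <- BulkExpressionSet(expr, unit = "RPKM", geneLengths = lengths,
                            sampleMeta = samples)
    truth <- new("SyntheticTruth", markerGenes = markerGenes,
                 confounderGenes = confounderGenes,
                 params = list(generator = "generateAtlas", nGenes = nGenes,
                               regions = regions, weeks = weeks,
                               markersPerRegion = markersPerRegion,
                               markerLog2FC = markerLog2FC, noiseSD = noiseSD,
                               seed = seed, confoundRegions = confoundRegions,
                               confoundersPerRegion = confoundersPerRegion,
                               minMarkerBaseline = minMarkerBaseline))
    list(expr = be, truth = truth)
  })
}

#' Generate synthetic bulk organoid count samples as regional mixtures
#'
#' Each sample's expected expression is a mixture of atlas region profiles
#' (per-region mean RPKM across weeks), weighted by the protocol's mixture
#' simplex. Expected counts are proportional to mixture RPKM times gene
#' length, scaled to the requested sequencing depth; additive batch shifts
#' are applied on the log2 scale before negative-binomial count draws.
#'
#' @param atlas the \code{expr} element returned by \code{\link{generateAtlas}}
#'   (unit RPKM with region annotations and gene lengths).
#' @param protocols character vector of protocol names.
#' @param samplesPerProtocol samples drawn per protocol.
#' @param mixtureSpec named list, protocol -> named non-negative vector over
#'   atlas regions summing to 1.
#' @param batchSpec NULL (single batch, no shift) or a list with elements
#'   \code{nBatches} (samples are assigned round-robin within protocol),
#'   \code{shifts} (named numeric per batch, additive log2 shift) and
#'   \code{affectedFraction} (fraction of genes the shift applies to,
#'   default 1).
#' @param depth expected total counts per sample.
#' @param dispersion negative-binomial dispersion (0 = Poisson).
#' @param countNoise set FALSE to emit the exact expected counts (noise-free
#'   construction checks).
#' @param seed integer seed.
#' @return list with \code{expr} (a \linkS4class{BulkExpressionSet}, unit
#'   counts, with protocol/batch annotations) and \code{truth} holding the
#'   per-sample mixture proportions and per-(batch, gene) log2 shifts.
#' @export
generateBulkOrganoids <- function(atlas, protocols, samplesPerProtocol,
                                  mixtureSpec, batchSpec = NULL,
                                  depth = 2e6, dispersion = 0.1,
                                  countNoise = TRUE, seed = 1) {
  stopifnot(is(atlas, "BulkExpressionSet"))
  regions <- unique(colData(atlas)$region)
  .stopIf(is.null(regions), "atlas must carry 'region' sample annotations")
  for (p in protocols) {
    w <- mixtureSpec[[p]]
    .stopIf(is.null(w), "no mixture given for protocol '%s'", p)
    .stopIf(any(w < 0) || abs(sum(w) - 1) > 1e-9,
            "mixture for '%s' is not a simplex", p)
    .stopIf(!all(names(w) %in% regions),
            "mixture regions for '%s' not all present in atlas", p)
  }
  v <- assay(atlas)
  profile <- vapply(regions, function(r)
    rowMeans(v[, colData(atlas)$region == r, drop = FALSE]),
    numeric(nrow(v)))
  len <- geneLengths(atlas)
  .stopIf(is.null(len), "atlas must carry gene lengths")

  nS <- samplesPerProtocol * length(protocols)
  sampleProtocol <- rep(protocols, each = samplesPerProtocol)
  sampleIds <- sprintf("%s_s%02d", sampleProtocol,
                       unlist(lapply(protocols, function(p)
                         seq_len(samplesPerProtocol))))
  if (!is.null(batchSpec)) {
    nB <- batchSpec$nBatches %||% length(batchSpec$shifts)
    batchLevels <- paste0("batch", seq_len(nB))
    sampleBatch <- unlist(lapply(protocols, function(p)
      rep(batchLevels, length.out = samplesPerProtocol)))
  } else {
    batchLevels <- "batch1"
    sampleBatch <- rep("batch1", nS)
  }

  .withSeed(.deriveSeed(seed, 12L), {
    genes <- rownames(v)
    shiftMat <- matrix(0, length(batchLevels), length(genes),
                       dimnames = list(batchLevels, genes))
    if (!is.null(batchSpec) && !is.null(batchSpec$shifts)) {
      frac <- batchSpec$affectedFraction %||% 1
      affected <- if (frac >= 1) genes else
        sample(genes, round(frac * length(genes)))
      for (b in names(batchSpec$shifts))
        shiftMat[b, affected] <- batchSpec$shifts[[b]]
    }
    mix <- matrix(0, nS, length(regions),
                  dimnames = list(sampleIds, regions))
    counts <- matrix(0, length(genes), nS,
                     dimnames = list(genes, sampleIds))
    for (j in seq_len(nS)) {
      w <- mixtureSpec[[sampleProtocol[j]]]
      mix[j, names(w)] <- w
      mu <- as.numeric(profile %*% mix[j, ])       # mixture RPKM
      muC <- mu * len                              # expected read mass
      muC <- muC / sum(muC) * depth
      muC <- muC * 2^shiftMat[sampleBatch[j], ]
      counts[, j] <- if (!countNoise) muC
        else if (dispersion > 0)
          stats::rnbinom(length(muC), mu = muC, size = 1 / dispersion)
        else stats::rpois(length(muC), muC)
    }
    be <- BulkExpressionSet(counts, unit = "counts", geneLengths = len,
                            sampleMeta = data.frame(protocol = sampleProtocol,
                                                    batch = sampleBatch))
    truth <- new("SyntheticTruth", mixtureProps = mix, batchShifts = shiftMat,
                 params = list(generator = "generateBulkOrganoids",
                               protocols = protocols,
                               samplesPerProtocol = samplesPerProtocol,
                               depth = depth, dispersion = dispersion,
                               seed = seed))
    list(expr = be, truth = truth)
  })
}

#' Generate a two-group negative-binomial count matrix with planted effects
#'
#' Convenience generator for calibrating the differential-expression stage:
#' gene baselines are lognormal, a fraction of genes receives a symmetric
#' log2 fold change between the groups (half up, half down), and counts are
#' negative-binomial.
#'
#' @param nGenes number of genes.
#' @param n1,n2 replicates per group.
#' @param dispersion NB dispersion (0 = Poisson).
#' @param deFraction fraction of genes with a planted effect (0 = pure null).
#' @param lfc planted absolute log2 fold change.
#' @param meanlog,sdlog lognormal baseline mean parameters.
#' @param seed integer seed.
#' @return list with \code{expr} (\linkS4class{BulkExpressionSet}, unit
#'   counts, \code{condition} annotation) and \code{truth} whose
#'   \code{markerGenes} list holds the planted \code{up} / \code{down} ids.
#' @export
generateDECounts <- function(nGenes = 2000, n1 = 4, n2 = 4, dispersion = 0.1,
                             deFraction = 0, lfc = 2, meanlog = log(50),
                             sdlog = 1, seed = 1) {
  .withSeed(.deriveSeed(seed, 13L), {
    genes <- sprintf("g%05d", seq_len(nGenes))
    base <- stats::rlnorm(nGenes, meanlog, sdlog)
    nDE <- round(deFraction * nGenes)
    up <- down <- character(0)
    lfcVec <- numeric(nGenes)
    if (nDE > 0) {
      de <- sample(nGenes, nDE)
      up <- genes[de[seq_len(ceiling(nDE / 2))]]
      down <- genes[de[-seq_len(ceiling(nDE / 2))]]
      lfcVec[match(up, genes)] <- lfc
      lfcVec[match(down, genes)] <- -lfc
    }
    mu1 <- base
    mu2 <- base * 2^lfcVec
    draw <- function(mu, n) {
      m <- vapply(seq_len(n), function(i)
        if (dispersion > 0)
          stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
        else stats::rpois(length(mu), mu), numeric(length(mu)))
      m
    }
    counts <- cbind(draw(mu1, n1), draw(mu2, n2))
    dimnames(counts) <- list(genes,
      c(sprintf("A_%02d", seq_len(n1)), sprintf("B_%02d", seq_len(n2))))
    be <- BulkExpressionSet(counts, unit = "counts",
            sampleMeta = data.frame(condition = rep(c("A", "B"), c(n1, n2))))
    truth <- new("SyntheticTruth",
                 markerGenes = list(up = up, down = down),
                 params = list(generator = "generateDECounts",
                               nGenes = nGenes, n1 = n1, n2 = n2,
                               dispersion = dispersion,
                               deFraction = deFraction, lfc = lfc,
                               seed = seed))
    list(expr = be, truth = truth)
  })
}
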