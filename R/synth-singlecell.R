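#' @include AllClasses.R utils.R
NULL

#' Generate a synthetic single-cell UMI dataset with planted structure
#'
#' Cells are drawn from a configurable number of cell types, each with its
#' own mean-expression program (a shared low baseline plus type-specific
#' marker genes at an elevated mean). UMI counts are Poisson (or negative
#' binomial) around the program scaled by a mild per-cell size factor.
#' Doublets are injected by summing the counts of two random singlet cells
#' (UMI counts add); batch structure is an optional per-(batch, gene) log2
#' shift; spliced/unspliced layers follow a steady-state kinetic model with
#' per-gene slope beta/gamma and planted induction / repression regimes.
#'
#' In the kinetic model, steady-state genes place every cell on the line
#' u = (beta/gamma) s. Induction genes put cells of the designated transient
#' types on the induction arm (unspliced leading: s reduced, u at the target
#' steady level, i.e. above the line); repression genes put transient cells
#' below the line (u collapsed ahead of s). All other cells sit on the line.
#'
#' @param nCells number of cells.
#' @param celltypeSpec list describing the programs: \code{nTypes} (>= 2),
#'   \code{nGenes}, \code{markersPerType}, \code{baseMean}, \code{markerMean},
#'   optional \code{proportions} (defaults to equal), \code{nMito} and
#'   \code{nRibo} housekeeping genes flagged in rowData. Alternatively a
#'   list with an explicit \code{programs} genes x types matrix.
#' @param doubletRate fraction of cells replaced by summed random pairs
#'   (in [0, 1)).
#' @param batches number of batches (cells assigned round-robin) or a
#'   character vector of per-cell batch labels.
#' @param batchEffectSD sd of per-(batch, gene) Gaussian log2 shifts applied
#'   to the expected counts (0 = no batch effect).
#' @param kineticsSpec NULL (no layers) or a list: \code{fracInduction},
#'   \code{fracRepression} (rest steady), \code{slopeRange} for beta/gamma,
#'   \code{transientTypes} (type indices forming the transient arm, default
#'   the first type, which is remodeled into a progenitor-like population
#'   expressing every type's markers at \code{progenitorMix} of their peak
#'   level so that transient kinetics are visible on all genes and the
#'   transient population remains separable in the embedding — neighborhood
#'   smoothing would otherwise average the deviations away),
#'   \code{noiseSD} (lognormal sd on layer values; 0 = exact means) and
#'   \code{layerScale} (multiplier taking programs to spliced means).
#' @param dispersion NB dispersion for counts (0 = Poisson).
#' @param seed integer seed.
#' @return list with \code{sce} (a \code{SingleCellExperiment}: assay
#'   \code{counts}, optional \code{spliced}/\code{unspliced}, colData
#'   \code{sample}/\code{batch}, rowData \code{is_mito}/\code{is_ribo}) and
#'   \code{truth} (\linkS4class{SyntheticTruth} with cell-type labels,
#'   doublet indices and kinetics).
#' @examples
#' sim <- generateSCDataset(nCells = 100,
#'   celltypeSpec = list(nTypes = 2, nGenes = 100, markersPerType = 10),
#'   seed = 1)
#' table(sim$truth@celltypeLabels)
#' @export
generateSCDataset <- function(nCells = 600,
                              celltypeSpec = list(nTypes = 5),
                              doubletRate = 0, batches = 1,
                              batchEffectSD = 0, kineticsSpec = NULL,
                              dispersion = 0, seed = 1) {
  .stopIf(doubletRate < 0 || doubletRate >= 1, "doubletRate must be in [0,1)")
  spec <- utils::modifyList(list(nTypes = 5, nGenes = 600, markersPerType = 40,
                                 baseMean = 0.2, markerMean = 3,
                                 nMito = 10, nRibo = 10,
                                 proportions = NULL, programs = NULL),
                            celltypeSpec)
  .withSeed(.deriveSeed(seed, 21L), {
    if (is.null(spec$programs)) {
      .stopIf(spec$nTypes < 2, "at least 2 cell types are required")
      nG <- spec$nGenes
      nT <- spec$nTypes
      hk <- spec$nMito + spec$nRibo
      .stopIf(spec$markersPerType * nT + hk > nG,
              "markers + housekeeping genes exceed nGenes")
      genes <- sprintf("G%04d", seq_len(nG))
      isMito <- isRibo <- rep(FALSE, nG)
      if (spec$nMito > 0) {
        mi <- nG - hk + seq_len(spec$nMito)
        genes[mi] <- sprintf("MT-%02d", seq_len(spec$nMito))
        isMito[mi] <- TRUE
      }
      if (spec$nRibo > 0) {
        ri <- nG - spec$nRibo + seq_len(spec$nRibo)
        genes[ri] <- sprintf("RPS%02d", seq_len(spec$nRibo))
        isRibo[ri] <- TRUE
      }
      programs <- matrix(spec$baseMean, nG, nT,
                         dimnames = list(genes, paste0("type", seq_len(nT))))
      idx <- 0L
      for (t in seq_len(nT)) {
        programs[idx + seq_len(spec$markersPerType), t] <- spec$markerMean
        idx <- idx + spec$markersPerType
      }
      programs[isMito | isRibo, ] <- spec$markerMean / 4
    } else {
      programs <- spec$programs
      genes <- rownames(programs)
      nG <- nrow(programs); nT <- ncol(programs)
      .stopIf(nT < 2, "at least 2 cell types are required")
      isMito <- grepl("^MT-", genes)
      isRibo <- grepl("^RP[SL]", genes)
    }
    typeNames <- colnames(programs)
    ks <- NULL
    if (!is.null(kineticsSpec)) {
      ks <- utils::modifyList(list(fracInduction = 1 / 3,
                                   fracRepression = 1 / 3,
                                   slopeRange = c(0.3, 1.5),
                                   transientTypes = 1L,
                                   progenitorMix = 0.4,
                                   noiseSD = 0.05, layerScale = 8),
                              kineticsSpec)
      for (tt in ks$transientTypes) {
        others <- setdiff(seq_len(nT), ks$transientTypes)
        peak <- apply(programs[, others, drop = FALSE], 1, max)
        programs[, tt] <- pmax(programs[, tt], ks$progenitorMix * peak)
      }
    }
    props <- spec$proportions %||% rep(1 / nT, nT)
    pool <- rep(typeNames, ceiling(props * nCells))
    cellType <- sample(pool)[seq_len(nCells)]
    cellIds <- sprintf("cell%05d", seq_len(nCells))

    if (is.character(batches) && length(batches) == nCells) {
      cellBatch <- batches
    } else {
      nB <- if (is.numeric(batches)) as.integer(batches) else 1L
      cellBatch <- rep(paste0("batch", seq_len(nB)), length.out = nCells)
    }
    batchLevels <- unique(cellBatch)
    bShift <- matrix(0, length(batchLevels), nG,
                     dimnames = list(batchLevels, genes))
    if (batchEffectSD > 0 && length(batchLevels) > 1) {
      for (b in batchLevels[-1])
        bShift[b, ] <- stats::rnorm(nG, 0, batchEffectSD)
    }

    sizeF <- exp(stats::rnorm(nCells, 0, 0.1))
    mu <- programs[, cellType, drop = FALSE] *
      2^t(bShift[cellBatch, , drop = FALSE])
    mu <- sweep(mu, 2, sizeF, "*")
    counts <- matrix(
      if (dispersion > 0)
        stats::rnbinom(length(mu), mu = as.numeric(mu), size = 1 / dispersion)
      else stats::rpois(length(mu), as.numeric(mu)),
      nG, nCells, dimnames = list(genes, cellIds))

    ## layers ---------------------------------------------------------------
    spliced <- unspliced <- NULL
    kinetics <- data.frame()
    if (!is.null(ks)) {
      slope <- stats::runif(nG, ks$slopeRange[1], ks$slopeRange[2])
      nInd <- round(ks$fracInduction * nG)
      nRep <- round(ks$fracRepression * nG)
      regime <- rep("steady", nG)
      ord <- sample(nG)
      regime[ord[seq_len(nInd)]] <- "induction"
      regime[ord[nInd + seq_len(nRep)]] <- "repression"
      transient <- cellType %in% typeNames[ks$transientTypes]
      m <- programs[, cellType, drop = FALSE] * ks$layerScale
      sMean <- m
      uMean <- m * slope
      if (any(transient)) {
        ind <- regime == "induction"
        rep_ <- regime == "repression"
        sMean[ind, transient] <- 0.35 * m[ind, transient]
        uMean[ind, transient] <- (slope * m)[ind, transient]   # above line
        sMean[rep_, transient] <- 0.4 * m[rep_, transient]
        uMean[rep_, transient] <- 0.1 * (slope * m)[rep_, transient] # below
      }
      noisy <- function(x) {
        if (ks$noiseSD > 0)
          x * exp(stats::rnorm(length(x), 0, ks$noiseSD))
        else x
      }
      spliced <- matrix(noisy(as.numeric(sMean)), nG, nCells,
                        dimnames = dimnames(counts))
      unspliced <- matrix(noisy(as.numeric(uMean)), nG, nCells,
                          dimnames = dimnames(counts))
      ## alpha = transcription rate (arbitrary units tied to program level);
      ## beta = splicing rate fixed at 1, so slope = beta/gamma and
      ## gammaTrue = beta/slope
      kinetics <- data.frame(gene = genes, alpha = unname(rowMeans(m)),
                             beta = 1, gammaTrue = 1 / slope,
                             regime = regime, stringsAsFactors = FALSE,
                             row.names = NULL)
    }

    ## doublets -------------------------------------------------------------
    doubletIdx <- integer(0)
    labels <- stats::setNames(cellType, cellIds)
    nDbl <- round(doubletRate * nCells)
    if (nDbl > 0) {
      doubletIdx <- sort(sample(nCells, nDbl))
      singlets <- setdiff(seq_len(nCells), doubletIdx)
      for (i in doubletIdx) {
        pair <- sample(singlets, 2)
        counts[, i] <- counts[, pair[1]] + counts[, pair[2]]
        if (!is.null(spliced)) {
          spliced[, i] <- spliced[, pair[1]] + spliced[, pair[2]]
          unspliced[, i] <- unspliced[, pair[1]] + unspliced[, pair[2]]
        }
        labels[i] <- paste(sort(cellType[pair]), collapse = "+")
      }
    }

    assays <- list(counts = as(counts, "CsparseMatrix"))
    if (!is.null(spliced)) {
      assays$spliced <- as(spliced, "CsparseMatrix")
      assays$unspliced <- as(unspliced, "CsparseMatrix")
    }
    sce <- SingleCellExperiment(
      assays = assays,
      colData = DataFrame(sample = rep("sample1", nCells), batch = cellBatch,
                          row.names = cellIds),
      rowData = DataFrame(is_mito = isMito, is_ribo = isRibo,
                          row.names = genes))
    truth <- new("SyntheticTruth", celltypeLabels = labels,
                 doubletIndices = as.integer(doubletIdx),
                 batchShifts = bShift, kinetics = kinetics,
                 params = list(generator = "generateSCDataset",
                               nCells = nCells, doubletRate = doubletRate,
                               batchEffectSD = batchEffectSD,
                               dispersion = dispersion, seed = seed,
                               celltypeSpec = spec[c("nTypes", "nGenes",
                                 "markersPerType", "baseMean", "markerMean")]))
    list(sce = sce, truth = truth)
  })
}
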