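#' @include AllClasses.R utils.R
NULL

.counts <- function(sce) assay(sce, "counts")

#' Quality-control filter for single-cell barcodes
#'
#' Removes barcodes with at least \code{maxUMI} total UMIs (high-count
#' barcodes are treated as likely multiplets), at least \code{maxMitoFrac}
#' mitochondrial UMI fraction, and — when \code{maxRiboFrac} is set — at
#' least that ribosomal fraction. All thresholds are exclusive-keep: a cell
#' is kept iff it is strictly below every bound.
#'
#' @param sce a \code{SingleCellExperiment} with a \code{counts} assay and
#'   \code{is_mito} (and \code{is_ribo} if used) flags in rowData.
#' @param maxUMI UMI bound (default 10000).
#' @param maxMitoFrac mitochondrial fraction bound (default 0.4).
#' @param maxRiboFrac optional ribosomal fraction bound (e.g. 0.15).
#' @param removeHighUMI set FALSE to keep high-UMI barcodes instead
#'   (the reading of "filtered" as removal is the default).
#' @return the filtered \code{SingleCellExperiment}; per-cell QC metrics
#'   (\code{total_umi}, \code{mito_frac}, \code{ribo_frac}) are added to
#'   colData.
#' @export
qcFilter <- function(sce, maxUMI = 10000, maxMitoFrac = 0.4,
                     maxRiboFrac = NULL, removeHighUMI = TRUE) {
  cts <- .counts(sce)
  rd <- rowData(sce)
  .stopIf(!"is_mito" %in% colnames(rd), "rowData is_mito flag required")
  tot <- Matrix::colSums(cts)
  mito <- Matrix::colSums(cts[rd$is_mito, , drop = FALSE]) / pmax(tot, 1)
  ribo <- if ("is_ribo" %in% colnames(rd))
    Matrix::colSums(cts[rd$is_ribo, , drop = FALSE]) / pmax(tot, 1)
  else rep(0, ncol(sce))
  keep <- mito < maxMitoFrac
  if (removeHighUMI) keep <- keep & tot < maxUMI
  if (!is.null(maxRiboFrac)) {
    .stopIf(!"is_ribo" %in% colnames(rd), "rowData is_ribo flag required")
    keep <- keep & ribo < maxRiboFrac
  }
  .stopIf(!any(keep), "QC filter removed every cell")
  colData(sce)$total_umi <- tot
  colData(sce)$mito_frac <- mito
  colData(sce)$ribo_frac <- ribo
  sce[, keep]
}

#' Median-total normalization with a log1p transform
#'
#' Scales each cell to a total count equal to the median of the
#' pre-normalization totals, then applies natural log(1 + x). The result is
#' stored in a \code{logcounts} assay.
#'
#' @param sce a \code{SingleCellExperiment} with a \code{counts} assay.
#' @return the \code{SingleCellExperiment} with \code{logcounts} added and
#'   the scale factor per cell in colData \code{size_factor}.
#' @export
normalizeLog1p <- function(sce) {
  cts <- .counts(sce)
  tot <- Matrix::colSums(cts)
  zero <- colnames(sce)[tot == 0]
  .stopIf(length(zero) > 0, "zero-total cell(s): %s",
          paste(utils::head(zero, 5), collapse = ", "))
  target <- stats::median(tot)
  sf <- tot / target
  norm <- sweep(as.matrix(cts), 2, sf, "/")
  assay(sce, "logcounts") <- log1p(norm)
  colData(sce)$size_factor <- sf
  sce
}

#' Select highly variable genes by binned dispersion
#'
#' Genes are binned into \code{nBins} equal-frequency bins of mean
#' normalized expression (means taken on the expm1 scale of the logcounts);
#' the dispersion (variance / mean) is z-scored within each bin, and the top
#' \code{n} genes by normalized dispersion among those with mean strictly
#' inside \code{(meanLo, meanHi)} are flagged.
#'
#' @param sce a \code{SingleCellExperiment} with \code{logcounts}.
#' @param n number of genes to flag (default 2000).
#' @param meanLo,meanHi eligibility bounds on the mean (defaults 0.005, 1.5).
#' @param nBins number of mean bins (default 20).
#' @return the \code{SingleCellExperiment} with logical rowData column
#'   \code{is_hvg} plus \code{hvg_mean} and \code{hvg_dispersion}.
#' @export
selectHVG <- function(sce, n = 2000, meanLo = 0.005, meanHi = 1.5,
                      nBins = 20) {
  .stopIf(!"logcounts" %in% SummarizedExperiment::assayNames(sce),
          "run normalizeLog1p first")
  x <- expm1(as.matrix(assay(sce, "logcounts")))
  mu <- rowMeans(x)
  v <- .rowVars(x)
  disp <- ifelse(mu > 0, v / mu, 0)
  pos <- mu > 0
  bins <- rep(NA_integer_, length(mu))
  if (sum(pos) >= 2) {
    br <- unique(stats::quantile(mu[pos], probs = seq(0, 1, length.out = nBins + 1)))
    bins[pos] <- as.integer(cut(mu[pos], breaks = br, include.lowest = TRUE))
  }
  normDisp <- rep(0, length(mu))
  for (b in unique(stats::na.omit(bins))) {
    i <- which(bins == b)
    m <- mean(disp[i]); s <- stats::sd(disp[i])
    normDisp[i] <- if (length(i) > 1 && isTRUE(s > 0)) (disp[i] - m) / s else 0
  }
  eligible <- mu > meanLo & mu < meanHi
  nEl <- sum(eligible)
  if (nEl < n) {
    warning(sprintf("only %d eligible genes (< %d requested); flagging all", nEl, n))
    n <- nEl
  }
  ord <- order(-normDisp, rownames(sce))
  ord <- ord[eligible[ord]]
  hvg <- rep(FALSE, nrow(sce))
  hvg[ord[seq_len(n)]] <- TRUE
  rowData(sce)$is_hvg <- hvg
  rowData(sce)$hvg_mean <- mu
  rowData(sce)$hvg_dispersion <- normDisp
  sce
}

#' Per-gene z-scoring with an upper clip
#'
#' Scales each gene to zero mean and unit variance across cells, then
#' truncates values above \code{clip} to \code{clip} (no lower truncation).
#' Zero-variance genes map to all zeros.
#'
#' @param x genes x cells matrix (e.g. logcounts, possibly subset to HVGs).
#' @param clip upper truncation (default 10).
#' @return scaled dense matrix, same shape.
#' @export
scaleClip <- function(x, clip = 10) {
  x <- as.matrix(x)
  mu <- rowMeans(x)
  s <- sqrt(.rowVars(x))
  out <- (x - mu) / ifelse(s > 0, s, 1)
  out[s == 0, ] <- 0
  out[out > clip] <- clip
  out
}

#' PCA embedding of cells
#'
#' Truncated SVD of the centered (cells x features) matrix. Axis signs are
#' fixed deterministically (the loading of largest magnitude on each
#' component is made positive), so the embedding is reproducible.
#'
#' @param x genes x cells matrix of scaled values.
#' @param nPcs number of components (default 50, capped at min(dim)).
#' @return list with \code{coords} (cells x nPcs), \code{varExplained}
#'   (non-increasing) and \code{rotation} (genes x nPcs).
#' @export
pcaEmbed <- function(x, nPcs = 50) {
  x <- as.matrix(x)
  nPcs <- as.integer(nPcs)
  .stopIf(nPcs > min(dim(x)), "nPcs (%d) exceeds min(genes, cells)", nPcs)
  xc <- x - rowMeans(x)             # center per gene
  sv <- svd(t(xc), nu = nPcs, nv = nPcs)
  coords <- sv$u %*% diag(sv$d[seq_len(nPcs)], nPcs)
  rot <- sv$v
  for (j in seq_len(nPcs)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      coords[, j] <- -coords[, j]
    }
  }
  rownames(coords) <- colnames(x)
  rownames(rot) <- rownames(x)
  colnames(coords) <- colnames(rot) <- paste0("PC", seq_len(nPcs))
  varExp <- sv$d[seq_len(nPcs)]^2 / max(ncol(x) - 1, 1)
  list(coords = coords, varExplained = varExp, rotation = rot)
}
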