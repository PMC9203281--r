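#' @include AllClasses.R utils.R bulk-normalize.R
NULL

#' Select the genes with the highest across-sample variance
#'
#' @param expr a \linkS4class{BulkExpressionSet} or matrix (genes x samples).
#' @param n number of genes to keep; ties are broken by gene id, making the
#'   selection deterministic.
#' @return character vector of gene ids, ordered by decreasing variance.
#' @export
selectTopVarianceGenes <- function(expr, n = 10000) {
  v <- if (is(expr, "BulkExpressionSet")) assay(expr) else as.matrix(expr)
  .stopIf(n > nrow(v), "n (%d) exceeds the number of genes (%d)", n, nrow(v))
  vars <- .rowVars(v)
  ord <- order(-vars, rownames(v))
  rownames(v)[ord][seq_len(n)]
}

## ---------------------------------------------------------------------------
## Empirical-Bayes batch adjustment (location/scale model, parametric priors)
## ---------------------------------------------------------------------------

## inverse-gamma moment-matching priors on the batch variances
.aprior <- function(d) { m <- mean(d); s2 <- stats::var(d); (2 * s2 + m^2) / s2 }
.bprior <- function(d) { m <- mean(d); s2 <- stats::var(d); (m * s2 + m^3) / s2 }

#' Fit an empirical-Bayes batch model
#'
#' Location/scale batch-effect model: genes are standardized with the
#' batch-size-weighted grand mean and the pooled variance of batch-regressed
#' residuals; per-(batch, gene) locations (gamma) and squared scales (delta)
#' are estimated on the standardized data and shrunk toward batch-level
#' parametric priors (normal for locations, inverse-gamma for scales) by
#' iterating the conditional posterior means to convergence.
#'
#' @param logExpr matrix of log-scale expression (genes x samples) or a
#'   \linkS4class{BulkExpressionSet}.
#' @param batch character/factor of batch labels, one per sample; at least
#'   two batches with at least two samples each.
#' @param tol convergence tolerance of the EB iteration; default 1e-4.
#' @param maxIter iteration cap.
#' @return a \linkS4class{BatchModel}.
#' @seealso \code{\link{applyComBat}}, \code{\link{batchLocationEffects}}
#' @export
fitComBat <- function(logExpr, batch, tol = 1e-4, maxIter = 200) {
  x <- if (is(logExpr, "BulkExpressionSet")) assay(logExpr) else
    as.matrix(logExpr)
  batch <- as.character(batch)
  .stopIf(length(batch) != ncol(x), "one batch label per sample required")
  levels <- unique(batch)
  .stopIf(length(levels) < 2, "at least 2 batches are required")
  nPer <- table(batch)
  .stopIf(any(nPer < 2), "batch(es) with a single sample: %s",
          paste(names(nPer)[nPer < 2], collapse = ", "))
  nG <- nrow(x); nS <- ncol(x)

  batchMeans <- vapply(levels, function(b)
    rowMeans(x[, batch == b, drop = FALSE]), numeric(nG))   # genes x batches
  w <- as.numeric(nPer[levels]) / nS
  grandMean <- as.numeric(batchMeans %*% w)
  fitted <- batchMeans[, match(batch, levels), drop = FALSE]
  varPooled <- rowSums((x - fitted)^2) / nS
  varPooled[varPooled <= 0] <- min(varPooled[varPooled > 0], 1e-8)
  z <- (x - grandMean) / sqrt(varPooled)

  gammaHat <- t(vapply(levels, function(b)
    rowMeans(z[, batch == b, drop = FALSE]), numeric(nG)))  # batches x genes
  deltaHat <- t(vapply(levels, function(b)
    .rowVars(z[, batch == b, drop = FALSE]), numeric(nG)))
  deltaHat[deltaHat <= 0] <- 1e-8

  gammaBar <- rowMeans(gammaHat)
  tau2 <- apply(gammaHat, 1, stats::var)
  aP <- apply(deltaHat, 1, .aprior)
  bP <- apply(deltaHat, 1, .bprior)

  gammaStar <- gammaHat
  deltaStar <- deltaHat
  iterations <- 0L
  for (i in seq_along(levels)) {
    n_b <- as.numeric(nPer[levels[i]])
    zb <- z[, batch == levels[i], drop = FALSE]
    gOld <- gammaHat[i, ]; dOld <- deltaHat[i, ]
    change <- Inf; it <- 0L
    sum2base <- rowSums(zb^2)
    sumz <- rowSums(zb)
    while (change > tol && it < maxIter) {
      gNew <- (n_b * tau2[i] * gammaHat[i, ] + dOld * gammaBar[i]) /
        (n_b * tau2[i] + dOld)
      sse <- sum2base - 2 * gNew * sumz + n_b * gNew^2
      dNew <- (0.5 * sse + bP[i]) / (n_b / 2 + aP[i] - 1)
      change <- max(abs(gNew - gOld) / pmax(abs(gOld), 1e-8),
                    abs(dNew - dOld) / pmax(abs(dOld), 1e-8))
      gOld <- gNew; dOld <- dNew; it <- it + 1L
    }
    gammaStar[i, ] <- gOld
    deltaStar[i, ] <- pmax(dOld, 1e-12)
    iterations <- max(iterations, it)
  }
  rownames(gammaStar) <- rownames(deltaStar) <- levels
  new("BatchModel", batches = levels, genes = rownames(x) %||%
        as.character(seq_len(nG)),
      gammaStar = gammaStar, deltaStar = deltaStar,
      grandMean = grandMean, varPooled = varPooled,
      priors = list(gammaBar = gammaBar, tau2 = tau2, aPrior = aP,
                    bPrior = bP, iterations = iterations))
}

#' Apply a fitted batch model
#'
#' Removes the shrunk batch location and scale from each sample and restores
#' the pooled mean/variance: \code{(x - mean - gamma* sd) / sqrt(delta*)}
#' rescaled back to the data scale.
#'
#' @param logExpr matrix or \linkS4class{BulkExpressionSet} with the same
#'   genes (and order) as at fit time.
#' @param model a \linkS4class{BatchModel} from \code{\link{fitComBat}}.
#' @param batch batch label per sample.
#' @return adjusted matrix (or \linkS4class{BulkExpressionSet}), same shape.
#' @export
applyComBat <- function(logExpr, model, batch) {
  x <- if (is(logExpr, "BulkExpressionSet")) assay(logExpr) else
    as.matrix(logExpr)
  gn <- rownames(x) %||% as.character(seq_len(nrow(x)))
  .stopIf(!identical(gn, model@genes),
          "gene set/order differs from the fitted model")
  batch <- as.character(batch)
  .stopIf(!all(batch %in% model@batches), "unknown batch label(s)")
  z <- (x - model@grandMean) / sqrt(model@varPooled)
  bi <- match(batch, model@batches)
  zAdj <- (z - t(model@gammaStar[bi, , drop = FALSE])) /
    sqrt(t(model@deltaStar[bi, , drop = FALSE]))
  out <- zAdj * sqrt(model@varPooled) + model@grandMean
  dimnames(out) <- dimnames(x)
  if (is(logExpr, "BulkExpressionSet")) {
    res <- logExpr
    assay(res) <- out
    res
  } else out
}

## ---------------------------------------------------------------------------
## Correspondence analysis
## ---------------------------------------------------------------------------

#' Correspondence analysis of a non-negative matrix
#'
#' SVD of the chi-square standardized residuals
#' \code{S = Dr^{-1/2} (P - r c') Dc^{-1/2}} of the correspondence matrix
#' \code{P = X / N}. Principal coordinates are returned for rows and columns
#' (both scaled by the singular values — the symmetric biplot variant); the
#' total inertia equals the Pearson chi-square statistic divided by the
#' grand total. Rows or columns with a zero marginal are dropped with a
#' warning. The sign of each axis is fixed by making the column coordinate
#' of largest magnitude positive.
#'
#' @param x non-negative matrix (or \linkS4class{BulkExpressionSet}).
#' @param k number of axes to retain (default 3, capped at min(dim) - 1).
#' @return a \linkS4class{CAResult}.
#' @examples
#' res <- correspondenceAnalysis(matrix(c(5, 0, 0, 5), 2, 2), k = 1)
#' totalInertia(res)   # chi-square / N = 1 for perfect association
#' @export
correspondenceAnalysis <- function(x, k = 3) {
  v <- if (is(x, "BulkExpressionSet")) assay(x) else as.matrix(x)
  .stopIf(any(v < 0), "correspondence analysis requires non-negative entries")
  zr <- rowSums(v) == 0; zc <- colSums(v) == 0
  if (any(zr) || any(zc)) {
    warning(sprintf("dropping %d all-zero rows and %d all-zero columns",
                    sum(zr), sum(zc)))
    v <- v[!zr, !zc, drop = FALSE]
  }
  .stopIf(min(dim(v)) < 2, "matrix too small after dropping zero margins")
  N <- sum(v)
  P <- v / N
  r <- rowSums(P); cc <- colSums(P)
  S <- (P - tcrossprod(r, cc)) / sqrt(tcrossprod(r, cc))
  sv <- svd(S)
  kMax <- min(dim(v)) - 1L
  k <- min(k, kMax)
  d <- sv$d[seq_len(kMax)]
  totIn <- sum(S^2)
  rowCo <- sweep(sv$u[, seq_len(k), drop = FALSE] %*%
                   diag(d[seq_len(k)], k), 1, sqrt(r), "/")
  colCo <- sweep(sv$v[, seq_len(k), drop = FALSE] %*%
                   diag(d[seq_len(k)], k), 1, sqrt(cc), "/")
  for (j in seq_len(k)) {
    i <- which.max(abs(colCo[, j]))
    if (colCo[i, j] < 0) {
      colCo[, j] <- -colCo[, j]
      rowCo[, j] <- -rowCo[, j]
    }
  }
  dimnames(rowCo) <- list(rownames(v) %||% paste0("row", seq_len(nrow(v))),
                          paste0("CA", seq_len(k)))
  dimnames(colCo) <- list(colnames(v) %||% paste0("col", seq_len(ncol(v))),
                          paste0("CA", seq_len(k)))
  new("CAResult", rowCoords = rowCo, colCoords = colCo,
      singularValues = d, totalInertia = totIn,
      axisInertia = if (totIn > 0) d[seq_len(k)]^2 / totIn else
        rep(0, k))
}

#' Integrate atlas and organoid expression matrices by correspondence analysis
#'
#' Merges the two RPKM matrices on their shared genes, quantile normalizes
#' the merged matrix, restricts to the top-variance genes, removes the
#' dataset-level batch effect with the empirical-Bayes model, and projects
#' the result into a low-dimensional subspace by correspondence analysis.
#' The input to the correspondence analysis is kept non-negative by clipping
#' any small negative values introduced by the batch adjustment to zero.
#'
#' @param atlas,organoids \linkS4class{BulkExpressionSet}s (RPKM) sharing
#'   gene ids.
#' @param nVarGenes number of top-variance genes (default 10000; capped at
#'   the shared gene count).
#' @param k number of correspondence-analysis axes (default 3).
#' @param batchAdjust adjust for dataset-of-origin as the batch (default
#'   TRUE).
#' @return list with \code{ca} (a \linkS4class{CAResult} whose column
#'   coordinates carry the merged samples), \code{sampleInfo} (data.frame
#'   with \code{dataset} plus the original annotations) and \code{genes}
#'   (the genes used).
#' @export
integrateAtlasOrganoids <- function(atlas, organoids, nVarGenes = 10000,
                                    k = 3, batchAdjust = TRUE) {
  shared <- intersect(rownames(atlas), rownames(organoids))
  .stopIf(length(shared) < 2, "fewer than 2 shared genes")
  a <- assay(atlas)[shared, , drop = FALSE]
  o <- assay(organoids)[shared, , drop = FALSE]
  .stopIf(any(duplicated(c(colnames(a), colnames(o)))),
          "sample ids collide between the two datasets")
  merged <- cbind(a, o)
  dataset <- rep(c("atlas", "organoid"), c(ncol(a), ncol(o)))
  qn <- quantileNormalize(merged)
  genes <- selectTopVarianceGenes(qn, min(nVarGenes, nrow(qn)))
  m <- qn[genes, , drop = FALSE]
  if (batchAdjust) {
    model <- fitComBat(m, dataset)
    m <- applyComBat(m, model, dataset)
    nneg <- sum(m < 0)
    if (nneg > 0) {
      message(sprintf("clipping %d negative values (%.2f%%) to zero for CA",
                      nneg, 100 * nneg / length(m)))
      m[m < 0] <- 0
    }
  }
  ca <- correspondenceAnalysis(m, k = k)
  info <- data.frame(dataset = dataset, row.names = colnames(merged))
  for (col in c("region", "week", "protocol", "batch")) {
    va <- if (col %in% colnames(colData(atlas)))
      as.character(colData(atlas)[[col]]) else rep(NA_character_, ncol(a))
    vo <- if (col %in% colnames(colData(organoids)))
      as.character(colData(organoids)[[col]]) else rep(NA_character_, ncol(o))
    info[[col]] <- c(va, vo)
  }
  ## samples can be dropped inside CA only via zero margins; align info
  info <- info[rownames(caCoords(ca, "columns")), , drop = FALSE]
  list(ca = ca, sampleInfo = info, genes = genes)
}
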