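#' @include AllClasses.R utils.R
NULL

#' Compute RPKM from raw counts
#'
#' Reads per kilobase of transcript per million mapped reads: each count is
#' divided by the gene length (bp) and the per-sample sequencing depth
#' (column sum of counts) and multiplied by 1e9.
#'
#' @param counts a \linkS4class{BulkExpressionSet} with unit \code{"counts"}
#'   and gene lengths in \code{rowData$gene_length}.
#' @param removeMito drop genes flagged \code{is_mito} in rowData before
#'   computing depth and RPKM (mirrors removal of mitochondrial genes ahead
#'   of normalization). Default TRUE when the flag is present.
#' @return A \linkS4class{BulkExpressionSet} with unit \code{"RPKM"}.
#' @examples
#' m <- matrix(c(100, 0), 2, 1, dimnames = list(c("a", "b"), "s1"))
#' be <- BulkExpressionSet(m, "counts", geneLengths = c(2000, 500))
#' # depth is 100 here; RPKM of gene a = 100 / (2000 * 100) * 1e9
#' assay(computeRPKM(be))
#' @export
computeRPKM <- function(counts, removeMito = TRUE) {
  stopifnot(is(counts, "BulkExpressionSet"))
  .stopIf(exprUnit(counts) != "counts",
          "computeRPKM expects unit 'counts', got '%s'", exprUnit(counts))
  if (removeMito && "is_mito" %in% colnames(rowData(counts)))
    counts <- counts[!rowData(counts)$is_mito, ]
  len <- geneLengths(counts)
  .stopIf(is.null(len), "gene lengths are required to compute RPKM")
  bad <- names(len)[is.na(len) | len <= 0]
  .stopIf(length(bad) > 0, "missing or non-positive gene length for: %s",
          paste(utils::head(bad, 5), collapse = ", "))
  v <- assay(counts)
  depth <- colSums(v)
  .stopIf(any(depth == 0), "zero-depth sample(s): %s",
          paste(colnames(v)[depth == 0], collapse = ", "))
  rpkm <- v / len / rep(depth, each = nrow(v)) * 1e9
  out <- counts
  assay(out) <- rpkm
  out@unit <- "RPKM"
  validObject(out)
  out
}

#' Rescale samples to a common RPKM sum
#'
#' Brings every sample (column) to the same total by rescaling; the target
#' total defaults to the mean of the original column sums, which preserves
#' the overall scale and treats samples symmetrically. Within-sample ratios
#' are untouched.
#'
#' @param expr a \linkS4class{BulkExpressionSet} (RPKM or FPKM).
#' @param target the common column sum; default mean of current column sums.
#' @return The rescaled \linkS4class{BulkExpressionSet}.
#' @export
equalSumNormalize <- function(expr, target = NULL) {
  stopifnot(is(expr, "BulkExpressionSet"))
  v <- assay(expr)
  .stopIf(ncol(v) < 1, "at least one sample required")
  s <- colSums(v)
  .stopIf(any(s == 0), "all-zero sample(s): %s",
          paste(colnames(v)[s == 0], collapse = ", "))
  if (is.null(target)) target <- mean(s)
  out <- expr
  assay(out) <- sweep(v, 2, target / s, "*")
  out
}

#' Log2 transform with a pseudocount
#'
#' @param expr a \linkS4class{BulkExpressionSet} with non-negative values.
#' @param pseudocount added before taking log2; default 1.
#' @return A \linkS4class{BulkExpressionSet} with unit \code{"log2"}.
#' @export
logTransform <- function(expr, pseudocount = 1) {
  stopifnot(is(expr, "BulkExpressionSet"))
  v <- assay(expr)
  .stopIf(any(v < 0), "negative values cannot be log-transformed")
  .stopIf(any(v + pseudocount <= 0),
          "pseudocount %g leaves non-positive values", pseudocount)
  out <- expr
  assay(out) <- log2(v + pseudocount)
  out@unit <- "log2"
  out
}

#' Quantile normalization across samples
#'
#' Forces every sample to the same empirical distribution (the row-wise mean
#' of the sorted columns); ties receive the mean of their target quantile
#' values (limma convention).
#'
#' @param merged a \linkS4class{BulkExpressionSet} or plain matrix with at
#'   least two samples.
#' @return Same type as the input, quantile normalized.
#' @export
quantileNormalize <- function(merged) {
  v <- if (is(merged, "BulkExpressionSet")) assay(merged) else as.matrix(merged)
  .stopIf(ncol(v) < 2, "quantile normalization needs >= 2 samples")
  qn <- limma::normalizeQuantiles(v, ties = TRUE)
  dimnames(qn) <- dimnames(v)
  if (is(merged, "BulkExpressionSet")) {
    out <- merged
    assay(out) <- qn
    out
  } else qn
}

#' Scale each row to a fixed range
#'
#' Affine map per row so that the row minimum maps to \code{lo} and the
#' maximum to \code{hi}; constant rows map to 0 (display convention for
#' heatmaps of relative expression).
#'
#' @param x matrix (or \linkS4class{BulkExpressionSet}) of log expression.
#' @param lo,hi target range, default [-0.5, 0.5].
#' @return numeric matrix of the same shape.
#' @export
scaleRowsToRange <- function(x, lo = -0.5, hi = 0.5) {
  v <- if (is(x, "BulkExpressionSet")) assay(x) else as.matrix(x)
  rmin <- matrixStats::rowMins(v)
  rmax <- matrixStats::rowMaxs(v)
  rng <- rmax - rmin
  out <- (v - rmin) / ifelse(rng == 0, 1, rng) * (hi - lo) + lo
  out[rng == 0, ] <- 0
  dimnames(out) <- dimnames(v)
  out
}
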