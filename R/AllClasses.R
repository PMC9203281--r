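#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowData colData<- rowData<- assay<-
#' @importFrom SingleCellExperiment SingleCellExperiment
NULL

.EXPR_UNITS <- c("counts", "RPKM", "FPKM", "log2", "scaled")

#' Bulk expression container with a unit tag
#'
#' A thin extension of \linkS4class{SummarizedExperiment} for bulk gene
#' expression matrices (genes in rows, samples in columns). The single extra
#' slot is a unit tag (\code{"counts"}, \code{"RPKM"}, \code{"FPKM"},
#' \code{"log2"} or \code{"scaled"}) that is only changed by the defined
#' normalization operations. Per-gene metadata (gene length in bp,
#' mitochondrial flag) lives in \code{rowData}; per-sample annotations
#' (region, week, protocol, batch) in \code{colData}.
#'
#' @slot unit character(1), the unit tag of the primary assay.
#' @export
setClass("BulkExpressionSet",
  contains = "SummarizedExperiment",
  representation(unit = "character"),
  prototype(unit = "counts")
)

setValidity("BulkExpressionSet", function(object) {
  msg <- NULL
  if (length(object@unit) != 1L || !object@unit %in% .EXPR_UNITS)
    msg <- c(msg, sprintf("'unit' must be one of %s",
                          paste(.EXPR_UNITS, collapse = ", ")))
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "gene ids must be unique")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be unique")
  if (length(assays(object)) >= 1L &&
      object@unit %in% c("counts", "RPKM", "FPKM")) {
    v <- assay(object, 1L)
    if (any(v < 0, na.rm = TRUE))
      msg <- c(msg, sprintf("negative values not allowed for unit '%s'",
                            object@unit))
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a BulkExpressionSet
#'
#' @param values numeric matrix, genes x samples, with row and column names.
#' @param unit unit tag of \code{values}.
#' @param geneLengths optional numeric vector of gene lengths in base pairs
#'   (named by gene or in row order).
#' @param sampleMeta optional data.frame of per-sample annotations (rows in
#'   column order of \code{values}); typical columns are \code{region},
#'   \code{week}, \code{protocol}, \code{batch}.
#' @param geneMeta optional data.frame of per-gene metadata.
#' @return A \linkS4class{BulkExpressionSet}.
#' @examples
#' m <- matrix(rpois(20, 10), 4, 5,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
#' be <- BulkExpressionSet(m, unit = "counts", geneLengths = rep(1000, 4))
#' exprUnit(be)
#' @export
BulkExpressionSet <- function(values, unit = "counts", geneLengths = NULL,
                              sampleMeta = NULL, geneMeta = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("gene", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("sample", seq_len(ncol(values)))
  rd <- if (is.null(geneMeta)) DataFrame(row.names = rownames(values))
        else DataFrame(geneMeta, row.names = rownames(values))
  if (!is.null(geneLengths)) {
    if (!is.null(names(geneLengths)))
      geneLengths <- geneLengths[rownames(values)]
    rd$gene_length <- as.numeric(geneLengths)
  }
  cd <- if (is.null(sampleMeta)) DataFrame(row.names = colnames(values))
        else DataFrame(sampleMeta, row.names = colnames(values))
  se <- SummarizedExperiment(assays = list(exprs = values),
                             rowData = rd, colData = cd)
  new("BulkExpressionSet", se, unit = unit)
}

#' Regional gene sets with derivation parameters
#'
#' Maps a brain region to the ordered list of genes whose atlas expression
#' exceeds a fold-change threshold in that region versus all others across a
#' developmental window. Produced by \code{\link{deriveRegionalMarkers}}.
#'
#' @slot sets named list of character vectors (region -> gene ids), pairwise
#'   disjoint.
#' @slot params list of the derivation parameters (fold-change threshold on
#'   the log2 scale, weeks used, excluded regions, confound regions and
#'   confound quantifier).
#' @export
setClass("RegionalGeneSets",
  representation(sets = "list", params = "list"))

setValidity("RegionalGeneSets", function(object) {
  g <- unlist(object@sets, use.names = FALSE)
  if (anyDuplicated(g))
    return("regional gene sets must be pairwise disjoint")
  if (is.null(names(object@sets)) || any(names(object@sets) == ""))
    return("sets must be named by region")
  TRUE
})

#' Correspondence analysis decomposition
#'
#' Principal-coordinate decomposition of a non-negative matrix via the SVD of
#' its chi-square standardized residuals. Total inertia equals the Pearson
#' chi-square statistic of the table divided by its grand total.
#'
#' @slot rowCoords genes x k principal coordinates.
#' @slot colCoords samples x k principal coordinates.
#' @slot singularValues non-increasing, non-negative singular values (all of
#'   them, not only the first k).
#' @slot totalInertia chi-square / N of the input table.
#' @slot axisInertia fraction of total inertia carried by each retained axis.
#' @export
setClass("CAResult",
  representation(rowCoords = "matrix", colCoords = "matrix",
                 singularValues = "numeric", totalInertia = "numeric",
                 axisInertia = "numeric"))

setValidity("CAResult", function(object) {
  d <- object@singularValues
  msg <- NULL
  if (any(d < -1e-12)) msg <- c(msg, "singular values must be non-negative")
  if (is.unsorted(rev(d), strictly = FALSE) && any(diff(d) > 1e-10))
    msg <- c(msg, "singular values must be non-increasing")
  if (object@totalInertia < -1e-12) msg <- c(msg, "total inertia must be >= 0")
  if (sum(object@axisInertia) > 1 + 1e-8)
    msg <- c(msg, "axis inertia fractions must sum to <= 1")
  if (is.null(msg)) TRUE else msg
})

#' Empirical-Bayes batch model
#'
#' Per (batch, gene) location and scale batch effects shrunk toward
#' batch-level parametric priors (normal prior for locations, inverse-gamma
#' for scales), in the style of the ComBat algorithm. Locations are stored on
#' the standardized scale; \code{\link{batchLocationEffects}} returns them on
#' the data scale.
#'
#' @slot batches character vector of batch levels.
#' @slot genes character vector of gene ids the model was fitted on.
#' @slot gammaStar batches x genes matrix of shrunk standardized locations.
#' @slot deltaStar batches x genes matrix of shrunk squared scales (> 0).
#' @slot grandMean per-gene weighted grand mean on the data scale.
#' @slot varPooled per-gene pooled (batch-regressed) variance.
#' @slot priors list of per-batch hyperparameters (gammaBar, tau2, aPrior,
#'   bPrior) and the iteration count.
#' @export
setClass("BatchModel",
  representation(batches = "character", genes = "character",
                 gammaStar = "matrix", deltaStar = "matrix",
                 grandMean = "numeric", varPooled = "numeric",
                 priors = "list"))

setValidity("BatchModel", function(object) {
  if (any(object@deltaStar <= 0))
    return("scale factors (deltaStar) must be > 0")
  TRUE
})

#' k-nearest-neighbor cell graph
#'
#' Symmetrized kNN graph over cells in an embedding, either plain Euclidean
#' or batch-balanced (a per-batch quota of neighbors for every cell).
#'
#' @slot cellIds character vector of cell ids (graph vertices).
#' @slot edges data.frame with columns \code{from}, \code{to} (integer vertex
#'   indices, from < to) and \code{weight} (> 0); no self edges.
#' @slot k neighbors requested per cell.
#' @slot mode \code{"plain"} or \code{"batch_balanced"}.
#' @slot nPcs dimensionality of the embedding the graph was built on.
#' @slot batch optional batch label per cell (batch-balanced mode).
#' @export
setClass("NeighborGraph",
  representation(cellIds = "character", edges = "data.frame",
                 k = "integer", mode = "character", nPcs = "integer",
                 batch = "character"))

setValidity("NeighborGraph", function(object) {
  e <- object@edges
  msg <- NULL
  if (nrow(e) > 0) {
    if (any(e$from == e$to)) msg <- c(msg, "self edges are not allowed")
    if (any(e$weight <= 0)) msg <- c(msg, "edge weights must be > 0")
    if (max(e$from, e$to) > length(object@cellIds))
      msg <- c(msg, "edge endpoints outside vertex set")
  }
  if (!object@mode %in% c("plain", "batch_balanced"))
    msg <- c(msg, "mode must be 'plain' or 'batch_balanced'")
  if (is.null(msg)) TRUE else msg
})

#' Steady-state RNA velocity result
#'
#' Per-gene degradation/steady-state slope \code{gamma} fitted through the
#' origin on neighborhood-smoothed spliced (Ms) and unspliced (Mu) moments,
#' with the per-cell velocity residual \code{Mu - gamma * Ms}.
#'
#' @slot gamma named per-gene slope (>= 0 for retained genes).
#' @slot velocity cells x genes matrix of residuals.
#' @slot Ms,Mu cells x genes smoothed moments of the retained genes.
#' @slot genes retained gene ids.
#' @export
setClass("VelocityResult",
  representation(gamma = "numeric", velocity = "matrix",
                 Ms = "matrix", Mu = "matrix", genes = "character"))

setValidity("VelocityResult", function(object) {
  msg <- NULL
  if (any(!is.finite(object@gamma)) || any(object@gamma < 0))
    msg <- c(msg, "gamma must be finite and >= 0 for retained genes")
  recon <- object@Mu - sweep(object@Ms, 2, object@gamma, "*")
  if (max(abs(recon - object@velocity)) > 1e-8)
    msg <- c(msg, "velocity must equal Mu - gamma * Ms")
  if (is.null(msg)) TRUE else msg
})

#' Planted ground truth of a synthetic dataset
#'
#' Ledger of everything a generator planted: regional marker genes, confound
#' decoys, per-sample regional mixture proportions, per-(batch, gene) log2
#' shifts, cell-type labels, injected doublet indices and per-gene kinetic
#' parameters. Round-trips losslessly through JSON via
#' \code{\link{writeTruth}} / \code{\link{readTruth}}.
#'
#' @slot markerGenes named list, region -> gene ids (pairwise disjoint).
#' @slot confounderGenes named list, confound region -> decoy gene ids.
#' @slot mixtureProps samples x regions matrix of simplex rows.
#' @slot batchShifts batches x genes matrix of additive log2-scale shifts.
#' @slot celltypeLabels named character, cell id -> type.
#' @slot doubletIndices integer indices of injected doublets.
#' @slot kinetics data.frame with columns gene, alpha, beta, gammaTrue,
#'   regime (steady/induction/repression).
#' @slot params list of the generator call parameters.
#' @export
setClass("SyntheticTruth",
  representation(markerGenes = "list", confounderGenes = "list",
                 mixtureProps = "matrix", batchShifts = "matrix",
                 celltypeLabels = "character", doubletIndices = "integer",
                 kinetics = "data.frame", params = "list"),
  prototype(markerGenes = list(), confounderGenes = list(),
            mixtureProps = matrix(numeric(0), 0, 0),
            batchShifts = matrix(numeric(0), 0, 0),
            celltypeLabels = character(0), doubletIndices = integer(0),
            kinetics = data.frame(), params = list()))

setValidity("SyntheticTruth", function(object) {
  msg <- NULL
  if (anyDuplicated(unlist(object@markerGenes, use.names = FALSE)))
    msg <- c(msg, "marker gene sets must be pairwise disjoint")
  if (nrow(object@mixtureProps) > 0) {
    s <- rowSums(object@mixtureProps)
    if (any(abs(s - 1) > 1e-9) || any(object@mixtureProps < 0))
      msg <- c(msg, "mixture proportions must be non-negative simplex rows")
  }
  if (is.null(msg)) TRUE else msg
})
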