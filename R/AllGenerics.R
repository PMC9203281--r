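#' @include AllClasses.R
NULL

#' Unit tag of an expression container
#' @param x a \linkS4class{BulkExpressionSet}.
#' @return character(1) unit tag.
#' @export
setGeneric("exprUnit", function(x) standardGeneric("exprUnit"))

#' @rdname exprUnit
#' @export
setMethod("exprUnit", "BulkExpressionSet", function(x) x@unit)

#' Gene lengths in base pairs
#' @param x a \linkS4class{BulkExpressionSet}.
#' @return numeric vector named by gene, or NULL when absent.
#' @export
setGeneric("geneLengths", function(x) standardGeneric("geneLengths"))

#' @rdname geneLengths
#' @export
setMethod("geneLengths", "BulkExpressionSet", function(x) {
  if (!"gene_length" %in% colnames(rowData(x))) return(NULL)
  stats::setNames(rowData(x)$gene_length, rownames(x))
})

#' Per-sample annotations as a data.frame
#' @param x a \linkS4class{BulkExpressionSet}.
#' @return data.frame with one row per sample.
#' @export
setGeneric("sampleMeta", function(x) standardGeneric("sampleMeta"))

#' @rdname sampleMeta
#' @export
setMethod("sampleMeta", "BulkExpressionSet",
          function(x) as.data.frame(colData(x)))

#' Gene sets of a RegionalGeneSets object
#' @param x a \linkS4class{RegionalGeneSets}.
#' @return named list of character vectors.
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname geneSets
#' @export
setMethod("geneSets", "RegionalGeneSets", function(x) x@sets)

#' Derivation / generator parameters stored in an object
#' @param x an object with a params slot.
#' @return list of parameters.
#' @export
setGeneric("derivationParams", function(x) standardGeneric("derivationParams"))

#' @rdname derivationParams
#' @export
setMethod("derivationParams", "RegionalGeneSets", function(x) x@params)

#' @rdname derivationParams
#' @export
setMethod("derivationParams", "SyntheticTruth", function(x) x@params)

#' Coordinates of a correspondence analysis
#' @param x a \linkS4class{CAResult}.
#' @param which \code{"columns"} (samples) or \code{"rows"} (genes).
#' @return matrix of principal coordinates.
#' @export
setGeneric("caCoords", function(x, which = c("columns", "rows"))
  standardGeneric("caCoords"))

#' @rdname caCoords
#' @export
setMethod("caCoords", "CAResult", function(x, which = c("columns", "rows")) {
  which <- match.arg(which)
  if (which == "columns") x@colCoords else x@rowCoords
})

#' Total inertia (chi-square / N) of a correspondence analysis
#' @param x a \linkS4class{CAResult}.
#' @return numeric(1).
#' @export
setGeneric("totalInertia", function(x) standardGeneric("totalInertia"))

#' @rdname totalInertia
#' @export
setMethod("totalInertia", "CAResult", function(x) x@totalInertia)

#' Data-scale batch location effects of a fitted batch model
#'
#' Returns the empirical-Bayes shrunk per-(batch, gene) additive location
#' effects expressed on the scale of the data the model was fitted on
#' (standardized locations multiplied by the pooled standard deviation).
#'
#' @param x a \linkS4class{BatchModel}.
#' @return batches x genes numeric matrix.
#' @export
setGeneric("batchLocationEffects",
           function(x) standardGeneric("batchLocationEffects"))

#' @rdname batchLocationEffects
#' @export
setMethod("batchLocationEffects", "BatchModel", function(x) {
  sweep(x@gammaStar, 2, sqrt(x@varPooled), "*")
})

#' Per-gene velocity slopes
#' @param x a \linkS4class{VelocityResult}.
#' @return named numeric vector of gamma values.
#' @export
setGeneric("velocityGamma", function(x) standardGeneric("velocityGamma"))

#' @rdname velocityGamma
#' @export
setMethod("velocityGamma", "VelocityResult", function(x) x@gamma)

#' Velocity residual matrix (cells x genes)
#' @param x a \linkS4class{VelocityResult}.
#' @return numeric matrix.
#' @export
setGeneric("velocityValues", function(x) standardGeneric("velocityValues"))

#' @rdname velocityValues
#' @export
setMethod("velocityValues", "VelocityResult", function(x) x@velocity)

## show methods -------------------------------------------------------------

setMethod("show", "BulkExpressionSet", function(object) {
  cat(sprintf("BulkExpressionSet: %d genes x %d samples [unit: %s]\n",
              nrow(object), ncol(object), object@unit))
  cn <- colnames(colData(object))
  if (length(cn)) cat("  sample annotations:", paste(cn, collapse = ", "), "\n")
})

setMethod("show", "RegionalGeneSets", function(object) {
  cat(sprintf("RegionalGeneSets: %d regions, %d genes total\n",
              length(object@sets), length(unlist(object@sets))))
  for (r in names(object@sets))
    cat(sprintf("  %s: %d genes\n", r, length(object@sets[[r]])))
})

setMethod("show", "CAResult", function(object) {
  k <- ncol(object@colCoords)
  cat(sprintf("CAResult: %d axes retained, total inertia %.4g\n",
              k, object@totalInertia))
  cat("  axis inertia fractions:",
      paste(sprintf("%.3f", object@axisInertia), collapse = " "), "\n")
})

setMethod("show", "BatchModel", function(object) {
  cat(sprintf("BatchModel: %d batches x %d genes (EB-shrunk, %d iterations)\n",
              length(object@batches), length(object@genes),
              object@priors$iterations %||% NA_integer_))
})

setMethod("show", "NeighborGraph", function(object) {
  cat(sprintf("NeighborGraph: %d cells, %d edges, k = %d, mode = %s\n",
              length(object@cellIds), nrow(object@edges), object@k,
              object@mode))
})

setMethod("show", "VelocityResult", function(object) {
  cat(sprintf("VelocityResult: %d cells x %d genes\n",
              nrow(object@velocity), length(object@genes)))
})

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:\n")
  if (length(object@markerGenes))
    cat(sprintf("  marker genes: %d regions (%d genes)\n",
                length(object@markerGenes),
                length(unlist(object@markerGenes))))
  if (nrow(object@mixtureProps))
    cat(sprintf("  mixtures: %d samples x %d regions\n",
                nrow(object@mixtureProps), ncol(object@mixtureProps)))
  if (length(object@celltypeLabels))
    cat(sprintf("  cells: %d (%d doublets)\n",
                length(object@celltypeLabels),
                length(object@doubletIndices)))
  if (nrow(object@kinetics))
    cat(sprintf("  kinetics: %d genes\n", nrow(object@kinetics)))
})
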