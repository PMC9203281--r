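#' @include AllClasses.R utils.R
#' @importFrom utils read.delim write.table
#' @importFrom Matrix readMM writeMM
NULL

#' Write a bulk expression matrix as TSV with sidecars
#'
#' Writes the genes x samples matrix as a TSV (gene ids in the first column,
#' header row of sample ids), a per-sample annotation TSV
#' (\code{<prefix>.samples.tsv}) and a small JSON sidecar holding the unit
#' tag and gene lengths (\code{<prefix>.meta.json}).
#'
#' @param expr a \linkS4class{BulkExpressionSet}.
#' @param prefix file path prefix; files \code{<prefix>.tsv},
#'   \code{<prefix>.samples.tsv} and \code{<prefix>.meta.json} are written.
#' @return invisibly, the paths written.
#' @export
writeExpressionTSV <- function(expr, prefix) {
  stopifnot(is(expr, "BulkExpressionSet"))
  mpath <- paste0(prefix, ".tsv")
  df <- data.frame(gene = rownames(expr), assay(expr), check.names = FALSE)
  write.table(df, mpath, sep = "\t", quote = FALSE, row.names = FALSE)
  spath <- paste0(prefix, ".samples.tsv")
  sm <- data.frame(sample = colnames(expr), as.data.frame(colData(expr)),
                   check.names = FALSE)
  write.table(sm, spath, sep = "\t", quote = FALSE, row.names = FALSE)
  jpath <- paste0(prefix, ".meta.json")
  meta <- list(unit = exprUnit(expr))
  gl <- geneLengths(expr)
  if (!is.null(gl)) meta$gene_lengths <- as.list(gl)
  jsonlite::write_json(meta, jpath, auto_unbox = TRUE, digits = NA)
  invisible(c(matrix = mpath, samples = spath, meta = jpath))
}

#' Read a bulk expression matrix written by writeExpressionTSV
#'
#' @param prefix file path prefix used at write time.
#' @return A \linkS4class{BulkExpressionSet}.
#' @export
readExpressionTSV <- function(prefix) {
  mpath <- paste0(prefix, ".tsv")
  df <- read.delim(mpath, check.names = FALSE, stringsAsFactors = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df[[1]]
  sm <- NULL
  spath <- paste0(prefix, ".samples.tsv")
  if (file.exists(spath)) {
    sdf <- read.delim(spath, check.names = FALSE, stringsAsFactors = FALSE)
    sm <- sdf[, setdiff(colnames(sdf), "sample"), drop = FALSE]
    rownames(sm) <- sdf$sample
    sm <- sm[colnames(v), , drop = FALSE]
  }
  unit <- "counts"; gl <- NULL
  jpath <- paste0(prefix, ".meta.json")
  if (file.exists(jpath)) {
    meta <- jsonlite::read_json(jpath, simplifyVector = TRUE)
    unit <- meta$unit %||% "counts"
    if (!is.null(meta$gene_lengths)) gl <- unlist(meta$gene_lengths)
  }
  BulkExpressionSet(v, unit = unit, geneLengths = gl, sampleMeta = sm)
}

#' Write gene sets in GMT format
#'
#' One set per line: name, description, then the member gene ids, all
#' tab-separated.
#'
#' @param sets a \linkS4class{RegionalGeneSets} or named list of character
#'   vectors.
#' @param path output file.
#' @param descriptions optional character vector of per-set descriptions; for
#'   a \linkS4class{RegionalGeneSets} the default is a digest of the
#'   derivation parameters.
#' @return invisibly, \code{path}.
#' @export
writeGMT <- function(sets, path, descriptions = NULL) {
  if (is(sets, "RegionalGeneSets")) {
    if (is.null(descriptions)) {
      p <- sets@params
      descriptions <- rep(sprintf("params_md5:%s",
        substr(.paramsDigest(p), 1, 12)), length(sets@sets))
    }
    sets <- sets@sets
  }
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

.paramsDigest <- function(p) {
  tf <- tempfile(); on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(p, auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file.
#' @return named list of character vectors (descriptions as attribute
#'   \code{"descriptions"}).
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) if (length(p) > 2) p[-(1:2)] else character(0))
  names(sets) <- vapply(parts, `[`, character(1), 1)
  attr(sets, "descriptions") <- vapply(parts, `[`, character(1), 2)
  sets
}

#' Write a single-cell dataset as a 10x-style MTX triple
#'
#' Writes \code{matrix.mtx}, \code{barcodes.tsv} and \code{features.tsv}
#' under \code{dir}, plus \code{spliced.mtx} / \code{unspliced.mtx} when the
#' corresponding assays are present.
#'
#' @param sce a \code{SingleCellExperiment} with a \code{counts} assay
#'   (genes x cells).
#' @param dir output directory (created if missing).
#' @return invisibly, \code{dir}.
#' @export
writeTenX <- function(sce, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeMM(as(as(assay(sce, "counts"), "CsparseMatrix"), "generalMatrix"),
          file.path(dir, "matrix.mtx"))
  writeLines(colnames(sce), file.path(dir, "barcodes.tsv"))
  feat <- data.frame(id = rownames(sce), name = rownames(sce))
  for (fl in c("is_mito", "is_ribo"))
    if (fl %in% colnames(rowData(sce))) feat[[fl]] <- rowData(sce)[[fl]]
  write.table(feat, file.path(dir, "features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  for (ly in c("spliced", "unspliced")) {
    if (ly %in% SummarizedExperiment::assayNames(sce))
      writeMM(as(as(assay(sce, ly), "CsparseMatrix"), "generalMatrix"),
              file.path(dir, paste0(ly, ".mtx")))
  }
  invisible(dir)
}

#' Read a 10x-style MTX triple into a SingleCellExperiment
#'
#' @param dir directory holding \code{matrix.mtx}, \code{barcodes.tsv},
#'   \code{features.tsv} and optionally \code{spliced.mtx} /
#'   \code{unspliced.mtx}.
#' @return a \code{SingleCellExperiment}.
#' @export
readTenX <- function(dir) {
  m <- as(readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  feat <- read.delim(file.path(dir, "features.tsv"), header = FALSE,
                     stringsAsFactors = FALSE)
  rownames(m) <- feat[[1]]
  colnames(m) <- barcodes
  assays <- list(counts = m)
  for (ly in c("spliced", "unspliced")) {
    f <- file.path(dir, paste0(ly, ".mtx"))
    if (file.exists(f)) {
      lm <- as(readMM(f), "CsparseMatrix")
      dimnames(lm) <- dimnames(m)
      assays[[ly]] <- lm
    }
  }
  rd <- DataFrame(row.names = rownames(m))
  if (ncol(feat) >= 3) rd$is_mito <- as.logical(feat[[3]])
  if (ncol(feat) >= 4) rd$is_ribo <- as.logical(feat[[4]])
  SingleCellExperiment(assays = assays, rowData = rd)
}

#' Serialize a SyntheticTruth ledger to JSON
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param path output JSON file.
#' @return invisibly, \code{path}.
#' @export
writeTruth <- function(truth, path) {
  stopifnot(is(truth, "SyntheticTruth"))
  obj <- list(
    marker_genes = truth@markerGenes,
    confounder_genes = truth@confounderGenes,
    mixture_props = .matrixToJSON(truth@mixtureProps),
    batch_shifts = .matrixToJSON(truth@batchShifts),
    celltype_labels = as.list(truth@celltypeLabels),
    doublet_indices = truth@doubletIndices,
    kinetics = truth@kinetics,
    params = truth@params
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

.matrixToJSON <- function(m) {
  if (length(m) == 0) return(NULL)
  list(rownames = rownames(m), colnames = colnames(m),
       values = unname(apply(m, 1, as.numeric, simplify = FALSE)))
}

.matrixFromJSON <- function(x) {
  if (is.null(x)) return(matrix(numeric(0), 0, 0))
  v <- do.call(rbind, lapply(x$values, unlist))
  rownames(v) <- unlist(x$rownames)
  colnames(v) <- unlist(x$colnames)
  v
}

#' Read a SyntheticTruth ledger from JSON
#'
#' @param path JSON file written by \code{\link{writeTruth}}.
#' @return a \linkS4class{SyntheticTruth}.
#' @export
readTruth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  kin <- if (length(obj$kinetics))
    do.call(rbind, lapply(obj$kinetics, function(r)
      data.frame(gene = r$gene, alpha = r$alpha, beta = r$beta,
                 gammaTrue = r$gammaTrue, regime = r$regime,
                 stringsAsFactors = FALSE)))
  else data.frame()
  new("SyntheticTruth",
      markerGenes = lapply(obj$marker_genes, function(x) unlist(x) %||% character(0)),
      confounderGenes = lapply(obj$confounder_genes, function(x) unlist(x) %||% character(0)),
      mixtureProps = .matrixFromJSON(obj$mixture_props),
      batchShifts = .matrixFromJSON(obj$batch_shifts),
      celltypeLabels = unlist(obj$celltype_labels) %||% character(0),
      doubletIndices = as.integer(unlist(obj$doublet_indices) %||% integer(0)),
      kinetics = kin,
      params = obj$params %||% list())
}
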