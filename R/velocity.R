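#' @include AllClasses.R utils.R sc-graph.R
NULL

#' Filter genes for RNA velocity
#'
#' Keeps genes with at least \code{minCounts} total spliced AND at least
#' \code{minCounts} total unspliced counts across all cells.
#'
#' @param spliced,unspliced genes x cells matrices (aligned).
#' @param minCounts threshold (default 30, inclusive).
#' @return character vector of retained gene ids.
#' @export
filterVelocityGenes <- function(spliced, unspliced, minCounts = 30) {
  .stopIf(!identical(dim(spliced), dim(unspliced)),
          "spliced and unspliced layers must be aligned")
  sTot <- Matrix::rowSums(spliced)
  uTot <- Matrix::rowSums(unspliced)
  keep <- sTot >= minCounts & uTot >= minCounts
  .stopIf(!any(keep), "no genes pass the velocity count filter")
  rownames(spliced)[keep]
}

#' Normalize spliced and unspliced layers independently
#'
#' Each layer is median-total normalized on its own (every cell scaled to
#' the layer's median pre-normalization total), then optionally log1p
#' transformed. Layers do not influence each other's scaling.
#'
#' @param spliced,unspliced genes x cells matrices.
#' @param log apply log1p after normalization (default TRUE, the standard
#'   preprocessing); use FALSE to keep the linear scale on which the
#'   kinetic ratio beta/gamma is defined.
#' @return list with normalized \code{spliced} and \code{unspliced}.
#' @export
normalizeLayers <- function(spliced, unspliced, log = TRUE) {
  normOne <- function(x, what) {
    tot <- Matrix::colSums(x)
    zero <- colnames(x)[tot == 0]
    .stopIf(length(zero) > 0, "zero-total cell(s) in %s layer: %s", what,
            paste(utils::head(zero, 5), collapse = ", "))
    out <- sweep(as.matrix(x), 2, tot / stats::median(tot), "/")
    if (log) log1p(out) else out
  }
  list(spliced = normOne(spliced, "spliced"),
       unspliced = normOne(unspliced, "unspliced"))
}

#' Smooth layers over cell neighborhoods (first-order moments)
#'
#' For each cell, each layer is averaged over the cell's neighborhood in
#' the kNN graph, with the cell itself included. Isolated cells fall back
#' to their own values with a warning.
#'
#' @param layers list with \code{spliced} and \code{unspliced} genes x cells
#'   matrices (normalized).
#' @param graph a \linkS4class{NeighborGraph} built on the velocity
#'   dataset's PCA (k = 30 in the reference setting).
#' @return list with \code{Ms} and \code{Mu}, cells x genes matrices.
#' @export
smoothMoments <- function(layers, graph) {
  s <- as.matrix(layers$spliced); u <- as.matrix(layers$unspliced)
  n <- ncol(s)
  .stopIf(length(graph@cellIds) != n, "graph does not match the layers")
  nbr <- neighborList(graph)
  iso <- sum(lengths(nbr) == 0)
  if (iso > 0)
    warning(sprintf("%d isolated cell(s) smoothed over themselves only", iso))
  Ms <- matrix(0, n, nrow(s), dimnames = list(colnames(s), rownames(s)))
  Mu <- Ms
  for (i in seq_len(n)) {
    hood <- c(i, nbr[[i]])
    Ms[i, ] <- rowMeans(s[, hood, drop = FALSE])
    Mu[i, ] <- rowMeans(u[, hood, drop = FALSE])
  }
  list(Ms = Ms, Mu = Mu)
}

#' Fit deterministic steady-state RNA velocity
#'
#' Per gene, the steady-state slope gamma is the least-squares fit of Mu on
#' Ms through the origin across all cells
#' (\code{gamma = <Mu, Ms> / <Ms, Ms>}); the velocity of a cell is its
#' deviation from that equilibrium line, \code{Mu - gamma * Ms}. Genes whose
#' smoothed spliced moment is all zero are dropped with a warning; negative
#' fitted slopes are floored at zero with a warning (configurable).
#'
#' @param Ms,Mu cells x genes smoothed moments from
#'   \code{\link{smoothMoments}}.
#' @param clipNegativeGamma floor negative slopes at 0 (default TRUE).
#' @return a \linkS4class{VelocityResult}.
#' @export
fitVelocity <- function(Ms, Mu, clipNegativeGamma = TRUE) {
  Ms <- as.matrix(Ms); Mu <- as.matrix(Mu)
  .stopIf(!identical(dim(Ms), dim(Mu)), "Ms and Mu must be aligned")
  ss <- colSums(Ms^2)
  drop <- ss == 0
  if (any(drop)) {
    warning(sprintf("dropping %d gene(s) with all-zero spliced moments",
                    sum(drop)))
    Ms <- Ms[, !drop, drop = FALSE]
    Mu <- Mu[, !drop, drop = FALSE]
    ss <- ss[!drop]
  }
  gamma <- colSums(Mu * Ms) / ss
  if (any(gamma < 0)) {
    if (clipNegativeGamma) {
      warning(sprintf("flooring %d negative gamma fit(s) at zero",
                      sum(gamma < 0)))
      gamma[gamma < 0] <- 0
    }
  }
  vel <- Mu - sweep(Ms, 2, gamma, "*")
  new("VelocityResult", gamma = stats::setNames(gamma, colnames(Ms)),
      velocity = vel, Ms = Ms, Mu = Mu, genes = colnames(Ms))
}

#' Mean velocity of one gene per cell type
#'
#' @param result a \linkS4class{VelocityResult}.
#' @param celltypes type label per cell (same order as the velocity rows).
#' @param gene retained gene id.
#' @return named numeric vector of per-type mean velocities.
#' @export
celltypeMeanVelocity <- function(result, celltypes, gene) {
  .stopIf(!gene %in% result@genes, "gene '%s' not retained in the fit", gene)
  v <- result@velocity[, gene]
  celltypes <- as.character(celltypes)
  .stopIf(length(celltypes) != length(v), "one label per cell required")
  vapply(split(v, celltypes), mean, numeric(1))
}
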