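#' @include AllClasses.R utils.R
NULL

#' Build a k-nearest-neighbor graph over an embedding
#'
#' Plain mode takes the k Euclidean nearest neighbors of each cell; the
#' batch-balanced mode takes ceiling(k / #batches) nearest neighbors within
#' every batch for every cell, so each cell is connected into all batches.
#' The directed kNN relation is symmetrized (union), and edges are weighted
#' with a Gaussian kernel \code{exp(-d^2 / (2 sigma^2))} whose bandwidth is
#' the median k-th-neighbor distance.
#'
#' @param embedding cells x dims matrix (e.g. from \code{\link{pcaEmbed}}).
#' @param k neighbors per cell (default 14).
#' @param mode \code{"plain"} or \code{"batch_balanced"}.
#' @param batch batch label per cell (required for batch-balanced mode).
#' @return a \linkS4class{NeighborGraph}.
#' @export
knnGraph <- function(embedding, k = 14, mode = c("plain", "batch_balanced"),
                     batch = NULL) {
  mode <- match.arg(mode)
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  .stopIf(k >= n, "k (%d) must be smaller than the number of cells (%d)", k, n)
  if (mode == "batch_balanced") {
    .stopIf(is.null(batch), "batch labels required for batch-balanced mode")
    .stopIf(length(batch) != n, "one batch label per cell required")
    batch <- as.character(batch)
  }
  d <- as.matrix(stats::dist(embedding))
  diag(d) <- Inf
  nbr <- matrix(0L, n, 0)
  kth <- numeric(n)
  if (mode == "plain") {
    nbrList <- lapply(seq_len(n), function(i) order(d[i, ])[seq_len(k)])
    kth <- vapply(seq_len(n), function(i) d[i, nbrList[[i]][k]], numeric(1))
  } else {
    levels <- unique(batch)
    kb <- ceiling(k / length(levels))
    nbrList <- lapply(seq_len(n), function(i) {
      unlist(lapply(levels, function(b) {
        j <- which(batch == b & seq_len(n) != i)
        j[order(d[i, j])][seq_len(min(kb, length(j)))]
      }))
    })
    kth <- vapply(seq_len(n), function(i)
      max(d[i, nbrList[[i]]]), numeric(1))
  }
  sigma <- stats::median(kth)
  if (!isTRUE(sigma > 0)) sigma <- 1
  from <- rep(seq_len(n), lengths(nbrList))
  to <- unlist(nbrList)
  lo <- pmin(from, to); hi <- pmax(from, to)
  keep <- !duplicated(cbind(lo, hi))
  lo <- lo[keep]; hi <- hi[keep]
  w <- exp(-d[cbind(lo, hi)]^2 / (2 * sigma^2))
  w <- pmax(w, 1e-12)
  ids <- rownames(embedding) %||% as.character(seq_len(n))
  new("NeighborGraph", cellIds = ids,
      edges = data.frame(from = lo, to = hi, weight = w),
      k = as.integer(k), mode = mode, nPcs = ncol(embedding),
      batch = if (is.null(batch)) character(0) else batch)
}

.asIgraph <- function(graph) {
  g <- igraph::make_empty_graph(n = length(graph@cellIds), directed = FALSE)
  g <- igraph::add_edges(g, rbind(graph@edges$from, graph@edges$to))
  igraph::E(g)$weight <- graph@edges$weight
  igraph::V(g)$name <- graph@cellIds
  g
}

#' Neighbor index list of a NeighborGraph
#'
#' @param graph a \linkS4class{NeighborGraph}.
#' @return list (one entry per cell) of integer neighbor indices under the
#'   symmetrized relation.
#' @export
neighborList <- function(graph) {
  n <- length(graph@cellIds)
  out <- vector("list", n)
  for (i in seq_len(n)) out[[i]] <- integer(0)
  e <- graph@edges
  for (r in seq_len(nrow(e))) {
    out[[e$from[r]]] <- c(out[[e$from[r]]], e$to[r])
    out[[e$to[r]]] <- c(out[[e$to[r]]], e$from[r])
  }
  out
}

#' Louvain community detection on a cell graph
#'
#' Modularity-maximizing partition of the weighted neighbor graph at the
#' given resolution (multi-level Louvain as implemented in igraph).
#' Labels are integers 0..C-1 ordered by decreasing cluster size, and the
#' run is deterministic under the seed.
#'
#' @param graph a \linkS4class{NeighborGraph}.
#' @param resolution resolution parameter (default 1; higher gives more,
#'   smaller clusters).
#' @param seed integer seed (default 0).
#' @return integer vector of cluster labels named by cell id.
#' @export
louvainCluster <- function(graph, resolution = 1, seed = 0) {
  .stopIf(length(graph@cellIds) == 0, "empty graph")
  g <- .asIgraph(graph)
  memb <- .withSeed(.deriveSeed(seed, 41L),
    igraph::membership(igraph::cluster_louvain(g, resolution = resolution)))
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
  out <- unname(relabel[as.character(memb)])
  stats::setNames(as.integer(out), graph@cellIds)
}
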