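#' @include AllClasses.R utils.R de.R
NULL

#' t-test with overestimated variance for single-cell groups
#'
#' Welch-style two-sample t-test of one focal group against the rest on
#' log-normalized expression, with both variance terms divided by the focal
#' group's size. Since the comparison group is usually much larger, this
#' overestimates its standard error and makes the test conservative
#' (|t| never exceeds the standard Welch statistic). Log2 fold changes are
#' computed on the expm1 scale of the group means with a small additive
#' guard.
#'
#' @param logcounts genes x cells matrix of log-normalized values.
#' @param groups group label per cell.
#' @param focalGroup the group tested against all remaining cells.
#' @param minFrac genes are tested only when expressed (> 0) in at least
#'   this fraction of the focal group or of the rest (default 0.01).
#' @return data.frame with \code{gene}, \code{log2FC} (focal over rest),
#'   \code{stat}, \code{p_value}, \code{q_value}, \code{mean_expression};
#'   attribute \code{"test"}.
#' @export
ttestOverestimVar <- function(logcounts, groups, focalGroup, minFrac = 0.01) {
  x <- as.matrix(logcounts)
  groups <- as.character(groups)
  .stopIf(length(groups) != ncol(x), "one group label per cell required")
  i1 <- groups == focalGroup
  .stopIf(sum(i1) < 2, "focal group needs >= 2 cells")
  .stopIf(sum(!i1) < 2, "comparison group needs >= 2 cells")
  f1 <- rowMeans(x[, i1, drop = FALSE] > 0)
  f0 <- rowMeans(x[, !i1, drop = FALSE] > 0)
  keep <- pmax(f1, f0) >= minFrac
  x <- x[keep, , drop = FALSE]
  n1 <- sum(i1)
  m1 <- rowMeans(x[, i1, drop = FALSE])
  m0 <- rowMeans(x[, !i1, drop = FALSE])
  v1 <- .rowVars(x[, i1, drop = FALSE])
  v0 <- .rowVars(x[, !i1, drop = FALSE])
  ## both variance terms use the focal group's size (overestimation)
  se2 <- v1 / n1 + v0 / n1
  tstat <- ifelse(se2 > 0, (m1 - m0) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n1)^2 / (n1 - 1)),
               1)
  p <- 2 * stats::pt(-abs(tstat), df = pmax(df, 1))
  lfc <- log2((expm1(m1) + 1e-9) / (expm1(m0) + 1e-9))
  out <- data.frame(gene = rownames(x), log2FC = lfc, stat = tstat,
                    p_value = p, q_value = bhAdjust(p),
                    mean_expression = rowMeans(x),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "test") <- sprintf("overestimated-variance t: %s vs rest",
                               focalGroup)
  out
}

#' Annotate clusters by correlation to a reference clustering
#'
#' Computes Pearson correlations between the cluster-mean scaled expression
#' vectors of a query and a reference dataset over a shared gene universe
#' (typically the union of per-dataset highly variable genes, each dataset
#' scaled and clipped on its own), and assigns every query cluster the
#' reference label of its best-correlated partner.
#'
#' @param scaledA genes x cells scaled matrix of the query dataset.
#' @param clustersA cluster label per query cell.
#' @param scaledB genes x cells scaled matrix of the reference dataset.
#' @param clustersB cluster label per reference cell.
#' @param genes shared gene universe (e.g. HVG union); must be present in
#'   both matrices.
#' @return list with \code{correlation} (A clusters x B clusters) and
#'   \code{assignment} (named character: A cluster -> best B cluster).
#' @export
clusterCorrelationAnnotate <- function(scaledA, clustersA, scaledB,
                                       clustersB, genes) {
  genes <- intersect(intersect(genes, rownames(scaledA)), rownames(scaledB))
  .stopIf(length(genes) == 0, "empty shared gene universe")
  meanBy <- function(x, cl) {
    cl <- as.character(cl)
    vapply(unique(cl), function(g)
      rowMeans(x[genes, cl == g, drop = FALSE]), numeric(length(genes)))
  }
  ma <- meanBy(scaledA, clustersA)
  mb <- meanBy(scaledB, clustersB)
  cors <- stats::cor(ma, mb)
  assignment <- colnames(mb)[apply(cors, 1, which.max)]
  names(assignment) <- colnames(ma)
  list(correlation = cors, assignment = assignment)
}
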