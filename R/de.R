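#' @include AllClasses.R utils.R
NULL

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: \code{q_i = min over j with p_(j) >= p_(i) of
#' m * p_(j) / j}, capped at 1.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return vector of q-values, same order as \code{p}.
#' @export
bhAdjust <- function(p) {
  .stopIf(any(p < 0 | p > 1, na.rm = TRUE), "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

## median-of-ratios size factors
.sizeFactors <- function(counts) {
  logGeo <- rowMeans(log(counts))
  use <- is.finite(logGeo)
  .stopIf(!any(use), "no gene is expressed in every sample")
  apply(counts, 2, function(col)
    exp(stats::median((log(col) - logGeo)[use & col > 0])))
}

## parametric mean-dispersion trend a0 + a1/mu, iteratively trimmed
.dispersionTrend <- function(mu, disp) {
  keep <- disp > 1e-7 & mu > 0
  if (sum(keep) < 10) return(function(m) rep(max(mean(disp), 1e-4), length(m)))
  a0 <- 0.01; a1 <- 1
  for (it in 1:4) {
    pred <- a0 + a1 / mu
    ratio <- disp / pred
    keep2 <- keep & ratio > 1e-4 & ratio < 15
    if (sum(keep2) < 10) break
    fit <- stats::lm(disp[keep2] ~ I(1 / mu[keep2]))
    a0 <- max(stats::coef(fit)[1], 1e-8)
    a1 <- max(stats::coef(fit)[2], 0)
  }
  function(m) a0 + a1 / pmax(m, 1e-8)
}

#' Negative-binomial Wald test for two-group differential expression
#'
#' A compact stand-in for the canonical bulk RNA-seq workflow: counts are
#' normalized with median-of-ratios size factors, per-gene NB dispersions are
#' estimated by method of moments and shrunk toward a parametric
#' mean-dispersion trend, and the log fold change of the group means is
#' tested with a Wald statistic whose standard error follows from the NB
#' variance function. Genes with zero counts in all samples are dropped with
#' a message. Output is not expected to be numerically identical to heavier
#' implementations (no outlier filtering, no independent filtering, no
#' fold-change shrinkage).
#'
#' @param counts \linkS4class{BulkExpressionSet} (unit counts) or matrix,
#'   genes x samples.
#' @param condition two-level factor/character, one label per sample; the
#'   log2 fold change is oriented second level over first (levels in order
#'   of first appearance).
#' @param priorWeight weight of the trend in the dispersion shrinkage
#'   (prior degrees of freedom); default 10.
#' @return data.frame with columns \code{gene}, \code{log2FC},
#'   \code{p_value}, \code{q_value}, \code{mean_expression} and an attribute
#'   \code{"test"} describing the comparison.
#' @export
nbWaldDE <- function(counts, condition, priorWeight = 10) {
  x <- if (is(counts, "BulkExpressionSet")) assay(counts) else
    as.matrix(counts)
  lv <- if (is.factor(condition)) levels(droplevels(condition)) else
    unique(as.character(condition))
  condition <- as.character(condition)
  .stopIf(length(condition) != ncol(x), "one condition label per sample")
  .stopIf(length(lv) != 2, "exactly two conditions are required")
  n1 <- sum(condition == lv[1]); n2 <- sum(condition == lv[2])
  .stopIf(n1 < 2 || n2 < 2, "each condition needs >= 2 replicates")

  keep <- rowSums(x) > 0
  if (any(!keep))
    message(sprintf("dropping %d genes with zero counts in all samples",
                    sum(!keep)))
  x <- x[keep, , drop = FALSE]
  sf <- .sizeFactors(x)
  q <- sweep(x, 2, sf, "/")
  i1 <- condition == lv[1]; i2 <- condition == lv[2]
  mu1 <- rowMeans(q[, i1, drop = FALSE])
  mu2 <- rowMeans(q[, i2, drop = FALSE])
  baseMean <- rowMeans(q)

  ## method-of-moments dispersion on normalized counts, pooled within groups
  v1 <- .rowVars(q[, i1, drop = FALSE]); v2 <- .rowVars(q[, i2, drop = FALSE])
  vPool <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  sInvMean <- mean(1 / sf)
  dispMom <- pmax((vPool - baseMean * sInvMean) / baseMean^2, 1e-8)
  trend <- .dispersionTrend(baseMean, dispMom)
  dispTr <- pmax(trend(baseMean), 1e-8)
  geneW <- n1 + n2 - 2
  disp <- exp((geneW * log(dispMom) + priorWeight * log(dispTr)) /
                (geneW + priorWeight))

  ## Wald statistic on the log ratio of group means (delta method):
  ## Var(K_i / s_i) = mu / s_i + disp * mu^2
  se2grp <- function(mu, idx, n) {
    rowSums(outer(1 / pmax(mu, 0.5), 1 / sf[idx], "*")) / n^2 + disp / n
  }
  se2 <- se2grp(mu1, i1, n1) + se2grp(mu2, i2, n2)
  lfc <- log2((mu2 + 0.5) / (mu1 + 0.5))
  lnFC <- log((mu2 + 0.5) / (mu1 + 0.5))
  z <- lnFC / sqrt(se2)
  ## t reference as a small-sample correction: the normal reference is
  ## anti-conservative at typical bulk replicate numbers, while the naive
  ## residual-df t is too conservative because the EB-stabilized dispersion
  ## contributes prior information; 2(n1+n2-2) holds the nominal level on
  ## negative-binomial nulls across the realistic dispersion range
  p <- 2 * stats::pt(-abs(z), df = 2 * (n1 + n2 - 2))
  out <- data.frame(gene = rownames(x), log2FC = lfc, p_value = p,
                    q_value = bhAdjust(p), mean_expression = baseMean,
                    stat = z, dispersion = disp,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "test") <- sprintf("NB Wald: %s vs %s", lv[2], lv[1])
  out
}

#' Threshold a differential-expression table into up/down gene lists
#'
#' @param de data.frame from \code{\link{nbWaldDE}} or
#'   \code{\link{ttestOverestimVar}}.
#' @param lfcMin minimum log2 fold change (default 1).
#' @param qMax strict upper bound on the q-value (default 0.05; a gene with
#'   q exactly equal to \code{qMax} is excluded).
#' @return list with character vectors \code{up} and \code{down}.
#' @export
significantGenes <- function(de, lfcMin = 1, qMax = 0.05) {
  sig <- de$q_value < qMax
  list(up = de$gene[sig & de$log2FC >= lfcMin],
       down = de$gene[sig & de$log2FC <= -lfcMin])
}
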