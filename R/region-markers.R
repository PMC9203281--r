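#' @include AllClasses.R utils.R
NULL

## mean RPKM per region at one week: replicate samples of the same
## region/week are averaged first, then regions are averaged symmetrically
.regionWeekMeans <- function(atlas, week) {
  cd <- colData(atlas)
  sel <- cd$week == week
  .stopIf(!any(sel), "week %s not present in atlas", week)
  v <- assay(atlas)[, sel, drop = FALSE]
  reg <- cd$region[sel]
  vapply(unique(reg), function(r)
    rowMeans(v[, reg == r, drop = FALSE]), numeric(nrow(v)))
}

#' Per-gene regional log2 fold change at one developmental week
#'
#' log2 of (mean RPKM in the region + 1) over (mean RPKM across all other
#' regions + 1), at the given week. Replicates of one region/week are
#' averaged before regions are compared; \code{excludedRegions} are left out
#' of the "all other regions" mean.
#'
#' @param atlas a \linkS4class{BulkExpressionSet} (RPKM) with
#'   \code{region}/\code{week} sample annotations.
#' @param region focal region.
#' @param week developmental week.
#' @param excludedRegions regions excluded from the comparison mean.
#' @param pseudocount added inside the ratio; default 1.
#' @return named numeric vector of per-gene log2 fold changes.
#' @export
regionalLog2FC <- function(atlas, region, week,
                           excludedRegions = character(0), pseudocount = 1) {
  rm_ <- .regionWeekMeans(atlas, week)
  .stopIf(!region %in% colnames(rm_), "region '%s' absent at week %s",
          region, week)
  others <- setdiff(colnames(rm_), c(region, excludedRegions))
  .stopIf(length(others) == 0,
          "no comparison regions left for '%s' after exclusions", region)
  otherMean <- rowMeans(rm_[, others, drop = FALSE])
  lfc <- log2((rm_[, region] + pseudocount) / (otherMean + pseudocount))
  stats::setNames(lfc, rownames(atlas))
}

#' Derive regional marker gene sets from a developmental atlas
#'
#' A gene is a marker of a region if its regional log2 fold change versus all
#' other regions (excluding \code{excludedRegions}) is at least
#' \code{fcThreshold} in \emph{every} week of the window. Genes specific to a
#' confound region (striatum/amygdala by default) are then filtered: a gene
#' is removed when its log2 fold change in a confound region versus all other
#' regions reaches the threshold in any week (\code{confoundQuantifier =
#' "any"}, conservative) or in all weeks (\code{"all"}). A gene qualifying in
#' more than one region is assigned to the region with the largest mean
#' across-week fold change, keeping the sets disjoint.
#'
#' @param atlas a \linkS4class{BulkExpressionSet} (RPKM) with
#'   \code{region}/\code{week} annotations.
#' @param weeks developmental window; default weeks 12 to 21.
#' @param fcThreshold log2 fold-change threshold (default 2, i.e. 4-fold).
#' @param excludedRegions regions excluded from the comparison mean and from
#'   receiving sets; default \code{c("striatum", "amygdala")} intersected
#'   with the atlas regions.
#' @param confoundRegions regions driving the confound filter; defaults to
#'   \code{excludedRegions}.
#' @param confoundQuantifier \code{"any"} (default) or \code{"all"} weeks.
#' @return a \linkS4class{RegionalGeneSets}.
#' @export
deriveRegionalMarkers <- function(atlas, weeks = 12:21, fcThreshold = 2,
                                  excludedRegions = c("striatum", "amygdala"),
                                  confoundRegions = NULL,
                                  confoundQuantifier = c("any", "all")) {
  confoundQuantifier <- match.arg(confoundQuantifier)
  cd <- colData(atlas)
  atlasWeeks <- intersect(weeks, unique(cd$week))
  .stopIf(length(atlasWeeks) == 0, "atlas has no samples in the week window")
  regions <- unique(cd$region)
  excludedRegions <- intersect(excludedRegions, regions)
  if (is.null(confoundRegions)) confoundRegions <- excludedRegions
  markerRegions <- setdiff(regions, excludedRegions)
  .stopIf(length(markerRegions) < 2,
          "need at least 2 candidate regions to compare")

  ## per region: min across-week FC decides membership; mean FC breaks ties
  minFC <- meanFC <- matrix(-Inf, nrow(atlas), length(markerRegions),
                            dimnames = list(rownames(atlas), markerRegions))
  for (r in markerRegions) {
    fc <- vapply(atlasWeeks, function(w)
      regionalLog2FC(atlas, r, w, excludedRegions), numeric(nrow(atlas)))
    minFC[, r] <- matrixStats::rowMins(fc)
    meanFC[, r] <- rowMeans(fc)
  }
  pass <- minFC >= fcThreshold

  ## confound filter: FC of the confound region vs all other regions
  confounded <- rep(FALSE, nrow(atlas))
  for (cr in confoundRegions) {
    if (!cr %in% regions) next
    fc <- vapply(atlasWeeks, function(w)
      regionalLog2FC(atlas, cr, w, character(0)), numeric(nrow(atlas)))
    hit <- if (confoundQuantifier == "any") matrixStats::rowMaxs(fc)
           else matrixStats::rowMins(fc)
    confounded <- confounded | (hit >= fcThreshold)
  }

  sets <- stats::setNames(vector("list", length(markerRegions)), markerRegions)
  assigned <- apply(pass & !confounded, 1, any)
  bestRegion <- markerRegions[max.col(meanFC, ties.method = "first")]
  for (r in markerRegions) {
    inR <- pass[, r] & !confounded & (bestRegion == r)
    sets[[r]] <- rownames(atlas)[inR]
  }
  new("RegionalGeneSets", sets = sets,
      params = list(fcThreshold = fcThreshold, weeks = atlasWeeks,
                    excludedRegions = excludedRegions,
                    confoundRegions = confoundRegions,
                    confoundQuantifier = confoundQuantifier))
}

#' Per-protocol fold changes of regional gene sets
#'
#' For every pair of protocols, computes each gene's difference of
#' protocol-mean log2(expression + 1) and summarizes the member genes of
#' each regional set.
#'
#' @param expr a \linkS4class{BulkExpressionSet} (RPKM/FPKM) with a
#'   \code{protocol} sample annotation.
#' @param sets a \linkS4class{RegionalGeneSets} or named list of gene ids.
#' @param pseudocount added before the log; default 1.
#' @return data.frame with one row per (protocol pair, regional set):
#'   \code{n_genes}, \code{mean_lfc}, \code{median_lfc}; the per-gene fold
#'   changes are attached as attribute \code{"perGene"} (a nested list).
#' @export
protocolRegionalFoldChange <- function(expr, sets, pseudocount = 1) {
  if (is(sets, "RegionalGeneSets")) sets <- geneSets(sets)
  cd <- colData(expr)
  .stopIf(is.null(cd$protocol), "expr must carry a 'protocol' annotation")
  protocols <- unique(cd$protocol)
  .stopIf(length(protocols) < 2, "need >= 2 protocols")
  lg <- log2(assay(expr) + pseudocount)
  pm <- vapply(protocols, function(p)
    rowMeans(lg[, cd$protocol == p, drop = FALSE]), numeric(nrow(lg)))
  pairs <- utils::combn(protocols, 2, simplify = FALSE)
  rows <- list(); perGene <- list()
  for (pr in pairs) {
    lfc <- pm[, pr[1]] - pm[, pr[2]]
    key <- paste(pr[1], "vs", pr[2])
    perGene[[key]] <- list()
    for (s in names(sets)) {
      members <- intersect(sets[[s]], rownames(lg))
      if (length(members) == 0) {
        warning(sprintf("gene set '%s' empty in the expression matrix; skipped", s))
        next
      }
      v <- lfc[members]
      perGene[[key]][[s]] <- v
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = key, set = s, n_genes = length(v),
        mean_lfc = mean(v), median_lfc = stats::median(v),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "perGene") <- perGene
  out
}

#' Venn-category z-scores of regional gene expression
#'
#' Partitions each regional gene set by differential-expression outcome
#' across the pairwise protocol comparisons: one category per protocol of
#' genes consistently upregulated in that protocol in every comparison it
#' appears in, plus the "shared" category of genes not significant in any
#' comparison. For each category the member genes' expression is summed over
#' the atlas samples of the set's own region across the week window, the
#' sums are averaged per category, and the averages are z-scored across the
#' categories of that set that hold at least \code{minGenes} genes
#' (population standard deviation by default). Categories below
#' \code{minGenes} carry \code{NA} z-scores.
#'
#' @param deResults named list of differential-expression tables (as returned
#'   by \code{\link{nbWaldDE}}); each name must be
#'   \code{"<protocolA>_vs_<protocolB>"} with log2 fold changes oriented
#'   A over B.
#' @param sets a \linkS4class{RegionalGeneSets} whose set names are atlas
#'   regions.
#' @param atlas a \linkS4class{BulkExpressionSet} with
#'   \code{region}/\code{week} annotations.
#' @param weeks week window for the expression sums; default 12 to 21.
#' @param minGenes minimum category size for a defined z-score; default 5.
#' @param lfcMin,qMax significance rule for "up" calls (defaults 1 and 0.05).
#' @param sdType \code{"population"} (divide by n) or \code{"sample"}.
#' @return data.frame with columns \code{set}, \code{category},
#'   \code{n_genes}, \code{mean_summed_expr}, \code{zscore}.
#' @export
vennCategoryZScore <- function(deResults, sets, atlas, weeks = 12:21,
                               minGenes = 5, lfcMin = 1, qMax = 0.05,
                               sdType = c("population", "sample")) {
  sdType <- match.arg(sdType)
  if (is(sets, "RegionalGeneSets")) sets <- geneSets(sets)
  comps <- strsplit(names(deResults), "_vs_", fixed = TRUE)
  .stopIf(any(lengths(comps) != 2),
          "deResults names must look like 'A_vs_B'")
  protocols <- unique(unlist(comps))

  upIn <- function(de, side) {
    sig <- de$q_value < qMax
    if (side == 1) de$gene[sig & de$log2FC >= lfcMin]
    else de$gene[sig & de$log2FC <= -lfcMin]
  }
  sigAny <- function(de) de$gene[de$q_value < qMax & abs(de$log2FC) >= lfcMin]

  allGenes <- unique(unlist(lapply(deResults, function(d) d$gene)))
  consistentUp <- lapply(protocols, function(p) {
    lists <- list()
    for (i in seq_along(deResults)) {
      pr <- comps[[i]]
      if (p == pr[1]) lists[[length(lists) + 1L]] <- upIn(deResults[[i]], 1)
      else if (p == pr[2]) lists[[length(lists) + 1L]] <- upIn(deResults[[i]], 2)
    }
    if (length(lists) == 0) character(0) else Reduce(intersect, lists)
  })
  names(consistentUp) <- protocols
  shared <- setdiff(allGenes,
                    unique(unlist(lapply(deResults, sigAny))))

  cd <- colData(atlas)
  wsel <- cd$week %in% weeks
  out <- list()
  for (s in names(sets)) {
    rsel <- wsel & cd$region == s
    .stopIf(!any(rsel), "no atlas samples for region '%s' in window", s)
    sums <- rowSums(assay(atlas)[, rsel, drop = FALSE])
    cats <- c(stats::setNames(lapply(protocols, function(p)
      intersect(sets[[s]], consistentUp[[p]])),
      paste0(protocols, "_specific_up")),
      list(shared = intersect(sets[[s]], shared)))
    n <- lengths(cats)
    avg <- vapply(cats, function(g)
      if (length(g)) mean(sums[g]) else NA_real_, numeric(1))
    defined <- n >= minGenes
    z <- rep(NA_real_, length(avg))
    if (sum(defined) >= 2) {
      a <- avg[defined]
      sdv <- if (sdType == "population")
        sqrt(mean((a - mean(a))^2)) else stats::sd(a)
      z[defined] <- if (sdv > 0) (a - mean(a)) / sdv else 0
    }
    out[[s]] <- data.frame(set = s, category = names(cats), n_genes = n,
                           mean_summed_expr = avg, zscore = z,
                           stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  .stopIf(all(res$n_genes < minGenes),
          "all categories hold fewer than %d genes", minGenes)
  res
}
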