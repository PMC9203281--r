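#' @include AllClasses.R utils.R de.R
NULL

#' Fisher's exact test for gene-set over-representation
#'
#' Two-sided exact test on the 2x2 table of selected vs gene-set membership
#' within a gene universe (the two-sided p sums the probabilities of all
#' tables no more likely than the observed one). The reported odds ratio is
#' the sample (cross-product) odds ratio, so an empty overlap gives 0.
#'
#' @param selected character vector of selected genes (subset of universe).
#' @param geneSet character vector; intersected with the universe.
#' @param universe character vector of all testable genes.
#' @return one-row data.frame: \code{overlap}, \code{set_size} (within the
#'   universe), \code{selected_size}, \code{universe_size}, \code{odds_ratio},
#'   \code{p_value}.
#' @examples
#' fisherEnrichment(letters[1:5], letters[1:5], letters[1:10])$p_value
#' # = 2/252, the probability of the only table as extreme as [[5,0],[0,5]]
#' @export
fisherEnrichment <- function(selected, geneSet, universe) {
  .stopIf(length(universe) == 0, "empty universe")
  universe <- unique(universe)
  selected <- intersect(unique(selected), universe)
  geneSet <- intersect(unique(geneSet), universe)
  a <- length(intersect(selected, geneSet))
  b <- length(selected) - a
  cc <- length(geneSet) - a
  d <- length(universe) - a - b - cc
  ## fisher.test can exceed 1 by floating-point accumulation
  p <- min(1, stats::fisher.test(matrix(c(a, b, cc, d), 2, 2))$p.value)
  orv <- if (b * cc == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * cc)
  if (a == 0) orv <- 0
  data.frame(overlap = a, set_size = a + cc, selected_size = a + b,
             universe_size = length(universe), odds_ratio = orv,
             p_value = p)
}

#' Fisher enrichment of a collection of gene sets
#'
#' @param selected selected genes.
#' @param sets \linkS4class{RegionalGeneSets} or named list of gene vectors.
#' @param universe gene universe.
#' @return data.frame, one row per set, ordered by p-value, with BH
#'   \code{q_value}.
#' @export
enrichGeneSets <- function(selected, sets, universe) {
  if (is(sets, "RegionalGeneSets")) sets <- geneSets(sets)
  rows <- lapply(names(sets), function(s) {
    r <- fisherEnrichment(selected, sets[[s]], universe)
    cbind(data.frame(set = s, stringsAsFactors = FALSE), r)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bhAdjust(out$p_value)
  out[order(out$p_value, -out$odds_ratio), , drop = FALSE]
}

#' Permutation gene-set enrichment on a ranked statistic
#'
#' Weighted Kolmogorov-Smirnov-style running enrichment score: genes are
#' ordered by decreasing statistic; set members add \code{|stat|} (normalized
#' by the in-set total), non-members subtract 1/(N - m). The enrichment score
#' is the extremum of the running sum; the null distribution comes from
#' permuting gene labels (drawing random sets of the same size), and the
#' two-sided p-value is \code{(1 + #{|ES_perm| >= |ES|}) / (nPerm + 1)}.
#'
#' @param stats named numeric vector of per-gene ranking statistics.
#' @param geneSet character vector (must overlap the ranking; >= 5 members
#'   after intersection by default).
#' @param nPerm number of permutations (default 1000).
#' @param seed integer seed for the permutation draw.
#' @param minSize minimum in-ranking set size.
#' @return one-row data.frame: \code{es}, \code{p_value}, \code{overlap},
#'   \code{set_size}, \code{universe_size}.
#' @export
gseaPermutation <- function(stats, geneSet, nPerm = 1000, seed = 1,
                            minSize = 5) {
  .stopIf(is.null(names(stats)), "stats must be named by gene")
  inSet <- names(stats) %in% geneSet
  m <- sum(inSet)
  .stopIf(m == 0, "gene set is disjoint from the ranking")
  .stopIf(m < minSize, "gene set has fewer than %d genes in the ranking",
          minSize)
  ord <- order(stats, decreasing = TRUE)
  s <- stats[ord]; hit <- inSet[ord]
  N <- length(s)
  esOf <- function(hit) {
    w <- abs(s) * hit
    tot <- sum(w)
    inc <- if (tot > 0) w / tot else hit / sum(hit)
    dec <- (!hit) / (N - sum(hit))
    run <- cumsum(inc - dec)
    run[which.max(abs(run))]
  }
  es <- esOf(hit)
  .withSeed(.deriveSeed(seed, 31L), {
    perm <- vapply(seq_len(nPerm), function(i) {
      h <- logical(N)
      h[sample.int(N, m)] <- TRUE
      esOf(h)
    }, numeric(1))
    p <- (1 + sum(abs(perm) >= abs(es))) / (nPerm + 1)
    data.frame(es = es, p_value = p, overlap = m, set_size = length(geneSet),
               universe_size = N)
  })
}
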