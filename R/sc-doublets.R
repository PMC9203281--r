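#' @include AllClasses.R utils.R sc-preprocess.R sc-graph.R
NULL

#' Score cells for doublets with simulated cell-pair profiles
#'
#' Per sample: synthetic doublets are simulated by summing the counts of
#' random pairs of observed cells (\code{simRatio} simulated per observed
#' cell), observed and simulated profiles are co-embedded (median-total
#' normalization, log1p, top-variance genes, z-scoring, PCA), and each
#' observed cell is scored from the fraction of simulated doublets among its
#' k nearest neighbors. The raw fraction is calibrated into a doublet
#' likelihood that accounts for the simulated:observed ratio and the
#' expected doublet rate, and cells above \code{threshold} are flagged.
#'
#' @param sce a \code{SingleCellExperiment} with \code{counts}; scored per
#'   level of colData \code{sample} when present.
#' @param expectedRate prior doublet rate (default 0.05).
#' @param threshold score above which a cell is flagged (default 0.2; must
#'   lie in (0, 1)).
#' @param simRatio simulated doublets per observed cell (default 2).
#' @param nPcs PCA dimensionality of the co-embedding (default 30).
#' @param k base neighbor count; default \code{round(0.5 * sqrt(n))},
#'   expanded by the simulated:observed ratio internally.
#' @param nTopVar number of top-variance genes used (default 1000).
#' @param seed integer seed.
#' @return data.frame with rownames = cell ids and columns \code{score} (in
#'   [0, 1]) and \code{is_doublet}.
#' @export
doubletScores <- function(sce, expectedRate = 0.05, threshold = 0.2,
                          simRatio = 2, nPcs = 30, k = NULL, nTopVar = 1000,
                          seed = 1) {
  .stopIf(threshold <= 0 || threshold >= 1, "threshold must be in (0, 1)")
  .stopIf(ncol(sce) < 100, "at least 100 cells are required")
  samples <- if ("sample" %in% colnames(colData(sce)))
    as.character(colData(sce)$sample) else rep("all", ncol(sce))
  out <- data.frame(score = rep(NA_real_, ncol(sce)),
                    is_doublet = NA, row.names = colnames(sce))
  for (s in unique(samples)) {
    idx <- which(samples == s)
    sc <- .doubletScoreOne(as.matrix(.counts(sce)[, idx, drop = FALSE]),
                           expectedRate, simRatio, nPcs, k, nTopVar,
                           .deriveSeed(seed, 51L + match(s, unique(samples))))
    out$score[idx] <- sc
  }
  out$is_doublet <- out$score > threshold
  out
}

.doubletScoreOne <- function(cts, expectedRate, simRatio, nPcs, k, nTopVar,
                             seed) {
  n <- ncol(cts)
  .withSeed(seed, {
    nSim <- round(simRatio * n)
    p1 <- sample.int(n, nSim, replace = TRUE)
    p2 <- sample.int(n, nSim, replace = TRUE)
    sim <- cts[, p1, drop = FALSE] + cts[, p2, drop = FALSE]
    ## UMI subsampling of the summed profiles: keeps the simulated doublets'
    ## per-gene sampling noise comparable to singlet depth, so that on
    ## homogeneous data the score stays near the calibrated prior instead of
    ## flagging the low-noise center of the cloud
    sim <- matrix(stats::rbinom(length(sim), size = as.integer(sim),
                                prob = 0.5),
                  nrow(sim), ncol(sim))
    colnames(sim) <- sprintf("sim%05d", seq_len(nSim))
    rownames(sim) <- rownames(cts)
    all <- cbind(cts, sim)
    tot <- colSums(all)
    norm <- sweep(all, 2, tot / stats::median(tot), "/")
    lg <- log1p(norm)
    vars <- .rowVars(lg[, seq_len(n), drop = FALSE])   # HVG on observed cells
    top <- order(-vars)[seq_len(min(nTopVar, nrow(lg)))]
    scaled <- scaleClip(lg[top, , drop = FALSE], clip = 10)
    npc <- min(nPcs, nrow(scaled) - 1L, ncol(scaled) - 1L)
    emb <- pcaEmbed(scaled, nPcs = npc)$coords
    if (is.null(k)) k <- max(3L, round(0.5 * sqrt(n)))
    r <- nSim / n
    kAdj <- max(3L, round(k * (1 + r)))
    d <- as.matrix(stats::dist(emb))
    diag(d) <- Inf
    isSim <- c(rep(FALSE, n), rep(TRUE, nSim))
    vapply(seq_len(n), function(i) {
      nbr <- order(d[i, ])[seq_len(kAdj)]
      q <- (sum(isSim[nbr]) + 1) / (kAdj + 2)   # regularized neighbor fraction
      rho <- expectedRate
      ld <- q * rho / r
      ls <- (1 - rho) * (1 - q)
      min(1, max(0, ld / (ld + ls)))
    }, numeric(1))
  })
}
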