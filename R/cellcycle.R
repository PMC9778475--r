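# Marker-based cell-cycle phase scoring and assignment.

#' Cell-cycle phase scores (binned-control scoring)
#'
#' Tirosh-style scoring of the S and G2M marker programs: genes are binned
#' by dataset-average expression (`nBins` equal-frequency bins) and each
#' marker gene contributes its expression minus the mean of `nCtrl`
#' control genes drawn from the same bin, so the score is robust to depth
#' and overall expression level. Expression is centred per gene before
#' scoring, so scores measure each cell relative to the dataset average:
#' identical cells score exactly 0.
#'
#' @param nm Normalized genes-by-cells matrix (or `SummarizedExperiment`
#'   with `logcounts`).
#' @param sGenes,g2mGenes Character vectors of S- and G2M-phase marker
#'   genes; each must intersect the gene universe.
#' @param nBins Number of expression bins (default 24).
#' @param nCtrl Control genes drawn per marker gene (default 100).
#' @param seed Seed for the control draws.
#' @return `data.frame(barcode, sScore, g2mScore, phase)` with the phase
#'   from [assignPhase()].
#' @export
phaseScores <- function(nm, sGenes, g2mGenes, nBins = 24, nCtrl = 100,
                        seed = 1) {
  nm <- if (is(nm, "SummarizedExperiment"))
    SummarizedExperiment::assay(nm, "logcounts") else nm
  genes <- rownames(nm)
  sGenes <- intersect(sGenes, genes)
  g2mGenes <- intersect(g2mGenes, genes)
  if (!length(sGenes) || !length(g2mGenes))
    stop("marker sets must intersect the gene universe")
  dn <- as.matrix(nm)
  avg <- rowMeans(dn)
  centred <- dn - avg
  nBins <- min(nBins, length(genes))
  bin <- ceiling(rank(avg, ties.method = "first") * nBins / length(genes))
  byBin <- split(genes, bin)
  scoreSet <- function(set, stream) withSeed(childSeed(seed, stream), {
    ctrl <- unique(unlist(lapply(set, function(g) {
      pool <- byBin[[as.character(bin[match(g, genes)])]]
      sample(pool, min(nCtrl, length(pool)))
    })))
    colMeans(centred[set, , drop = FALSE]) -
      colMeans(centred[ctrl, , drop = FALSE])
  })
  s <- scoreSet(sGenes, 1L)
  g2m <- scoreSet(g2mGenes, 2L)
  data.frame(barcode = colnames(nm), sScore = as.numeric(s),
             g2mScore = as.numeric(g2m),
             phase = assignPhase(s, g2m), row.names = NULL)
}

#' Assign cell-cycle phases from S/G2M scores
#'
#' A cell is G1 when neither score is positive; otherwise it takes the
#' phase of the larger score, ties broken toward S.
#'
#' @param sScore,g2mScore Numeric score vectors (finite).
#' @return Character vector over `{"G1", "S", "G2M"}`.
#' @examples
#' assignPhase(c(-0.1, 0.5, 0.3), c(-0.2, 0.1, 0.3))  # G1 S S
#' @export
assignPhase <- function(sScore, g2mScore) {
  stopifnot(all(is.finite(sScore)), all(is.finite(g2mScore)),
            length(sScore) == length(g2mScore))
  phase <- rep("G1", length(sScore))
  phase[sScore > 0 & sScore >= g2mScore] <- "S"
  phase[g2mScore > 0 & g2mScore > sScore] <- "G2M"
  phase
}

#' Per-group cell-cycle phase fractions
#'
#' Counts and percentages of cells in each phase per group, in the layout
#' of a phases-by-treatment summary table.
#'
#' @param phases Phase label per cell (`G1`/`S`/`G2M`).
#' @param groups Group label per cell.
#' @return `data.frame(group, phase, count, percent)` with percentages of
#'   the group total rounded to 2 decimals.
#' @examples
#' phaseFractions(rep(c("G1", "S", "G2M"), c(344, 671, 340)),
#'                rep("ctr", 1355))
#' @export
phaseFractions <- function(phases, groups) {
  stopifnot(length(phases) == length(groups))
  out <- do.call(rbind, lapply(unique(as.character(groups)), function(g) {
    ph <- phases[groups == g]
    counts <- vapply(c("G1", "S", "G2M"), function(p) sum(ph == p),
                     integer(1))
    data.frame(group = g, phase = c("G1", "S", "G2M"),
               count = as.integer(counts),
               percent = round(100 * counts / length(ph), 2))
  }))
  rownames(out) <- NULL
  out
}
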