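# GSEA-style weighted running-sum enrichment and per-cell NES projection.

# Core running-sum statistic given hit positions in the ranked list.
# `hitWeights` are the (already |score|^weight) raw weights of the hits in
# rank order; misses decrement 1/(N - k). Returns ES and the index of the
# extremum among hit positions (for the leading edge).
.esFromPositions <- function(pos, hitWeights, N) {
  k <- length(pos)
  if (k == 0L) stop("gene set does not intersect the ranked universe")
  if (k >= N) stop("gene set equal to (or exceeding) the universe")
  wsum <- sum(hitWeights)
  w <- if (wsum > 0) hitWeights / wsum else rep(1 / k, k)
  missStep <- 1 / (N - k)
  cumw <- cumsum(w)
  atHit <- cumw - (pos - seq_len(k)) * missStep
  beforeHit <- c(0, cumw[-k]) - (pos - seq_len(k)) * missStep
  hi <- max(atHit); lo <- min(beforeHit, 0)
  # on an exact tie in absolute deviation the positive extremum is taken
  # (tolerance absorbs float noise in the rational running sums)
  if (hi >= -lo - 1e-9) list(es = hi, extremum = which.max(atHit), sign = 1)
  else list(es = lo, extremum = which.min(beforeHit), sign = -1)
}

#' GSEA enrichment score
#'
#' Weighted Kolmogorov-Smirnov-style running sum: genes are ranked by
#' decreasing score (ties broken by gene identifier); each set gene
#' ("hit") increments the running sum proportionally to
#' `|score|^weight` (normalized to 1 over the hits, equal increments when
#' all hit scores are zero), each miss decrements `1/(N - |set|)`. The
#' enrichment score is the running-sum value of maximal absolute
#' deviation (ties between the positive and negative extremum resolve to
#' the positive one); the leading edge contains the hits up to the
#' sign-appropriate extremum.
#'
#' @param scores Named numeric vector: per-gene signature scores.
#' @param set Character vector of member genes (or a 1-element named list).
#' @param weight Exponent on |score| for hit increments (default 1;
#'   0 gives the unweighted Kolmogorov-Smirnov form).
#' @return List with `es` (in \[-1, 1\]), `running` (full running sum,
#'   one value per ranked gene) and `leadingEdge`.
#' @examples
#' s <- c(a = 3, b = 2, c = 1, d = 0.5)
#' gseaES(s, c("a", "b"), weight = 0)$es
#' @export
gseaES <- function(scores, set, weight = 1) {
  if (is.list(set)) set <- unlist(set)
  if (is.null(names(scores))) stop("scores must be named by gene")
  ord <- order(-scores, names(scores))
  rnames <- names(scores)[ord]
  rscores <- scores[ord]
  hit <- rnames %in% set
  pos <- which(hit)
  k <- length(pos); N <- length(scores)
  res <- .esFromPositions(pos, abs(rscores[pos])^weight, N)
  # full running sum for inspection/plotting
  inc <- rep(-1 / (N - k), N)
  wraw <- abs(rscores[pos])^weight
  inc[pos] <- if (sum(wraw) > 0) wraw / sum(wraw) else 1 / k
  running <- cumsum(inc)
  names(running) <- rnames
  le <- if (res$sign > 0) rnames[pos[seq_len(res$extremum)]]
        else rnames[pos[seq(res$extremum, k)]]
  list(es = res$es, running = running, leadingEdge = le)
}

#' GSEA normalized enrichment score with permutation p-value
#'
#' The null distribution is built from `nPerm` random gene sets of the
#' same size drawn from the ranked universe (gene-permutation null). The
#' NES divides the observed ES by the mean |null ES| of matching sign; the
#' p-value is `(1 + #[|null ES| >= |ES|]) / (1 + nPerm)`, never exactly 0.
#'
#' @inheritParams gseaES
#' @param nPerm Number of null sets (>= 100).
#' @param seed Seed; results are deterministic given it.
#' @return List with `es`, `nes`, `pval`, `leadingEdge`.
#' @export
gseaNES <- function(scores, set, weight = 1, nPerm = 1000, seed = 1) {
  if (nPerm < 100) stop("nPerm must be >= 100")
  obs <- gseaES(scores, set, weight)
  ord <- order(-scores, names(scores))
  rscores <- scores[ord]
  N <- length(scores)
  k <- sum(names(scores)[ord] %in% (if (is.list(set)) unlist(set) else set))
  nulls <- withSeed(seed, vapply(seq_len(nPerm), function(i) {
    pos <- sort(sample.int(N, k))
    .esFromPositions(pos, abs(rscores[pos])^weight, N)$es
  }, numeric(1)))
  if (all(nulls == 0)) stop("degenerate null distribution (all zero)")
  nes <- if (obs$es > 0) {
    denom <- mean(nulls[nulls > 0])
    if (!is.finite(denom) || denom == 0)
      stop("degenerate null distribution for positive ES")
    obs$es / denom
  } else if (obs$es < 0) {
    denom <- mean(abs(nulls[nulls < 0]))
    if (!is.finite(denom) || denom == 0)
      stop("degenerate null distribution for negative ES")
    obs$es / denom
  } else 0
  pval <- (1 + sum(abs(nulls) >= abs(obs$es))) / (1 + nPerm)
  list(es = obs$es, nes = nes, pval = pval,
       leadingEdge = obs$leadingEdge)
}

#' Per-cell centered signatures
#'
#' Each cell's score for a gene is its normalized expression minus the
#' dataset mean for that gene, i.e. the cell's profile relative to the
#' average of the dataset.
#'
#' @param nm Normalized genes-by-cells matrix (or `SummarizedExperiment`
#'   with `logcounts`); >= 2 cells.
#' @return Dense genes x cells matrix of centered scores (rows sum to 0
#'   across cells).
#' @export
perCellSignatures <- function(nm) {
  nm <- if (is(nm, "SummarizedExperiment"))
    SummarizedExperiment::assay(nm, "logcounts") else nm
  if (ncol(nm) < 2) stop("per-cell signatures need at least 2 cells")
  dn <- as.matrix(nm)
  dn - rowMeans(dn)
}

#' Per-cell gene-set enrichment (cells x pathways NES matrix)
#'
#' Runs [gseaNES()] on every (cell, set) pair of a per-cell signature
#' matrix. Cells whose signature is identically zero get NES 0 for every
#' set by convention.
#'
#' @param signatures Genes x cells matrix of per-cell scores (from
#'   [perCellSignatures()]).
#' @param sets Named list of gene sets.
#' @param weight,nPerm See [gseaNES()].
#' @param seed Master seed; each (cell, set) pair uses a derived seed.
#' @return Cells x sets numeric matrix of NES values.
#' @export
perCellEnrichment <- function(signatures, sets, weight = 1, nPerm = 1000,
                              seed = 1) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  out <- matrix(0, ncol(signatures), length(sets),
                dimnames = list(colnames(signatures), names(sets)))
  for (ci in seq_len(ncol(signatures))) {
    s <- signatures[, ci]
    names(s) <- rownames(signatures)
    if (all(s == 0)) next
    for (si in seq_along(sets)) {
      out[ci, si] <- gseaNES(s, sets[[si]], weight = weight,
                             nPerm = nPerm,
                             seed = childSeed(seed, ci * 131L + si))$nes
    }
  }
  out
}
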