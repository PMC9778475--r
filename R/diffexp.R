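#' Per-gene two-group Wilcoxon rank-sum test
#'
#' Two-sided p-value per gene from the normal approximation to the
#' rank-sum statistic, with tie correction (mandatory at single-cell zero
#' inflation) and continuity correction. Genes fully tied across both
#' groups get p = 1.
#'
#' @param nm Normalized genes-by-cells matrix (or `SummarizedExperiment`
#'   with `logcounts`).
#' @param groups Two-level label per cell; both levels need >= 3 cells.
#' @return Named numeric vector of raw p-values, one per gene.
#' @export
wilcoxonDE <- function(nm, groups) {
  nm <- if (is(nm, "SummarizedExperiment"))
    SummarizedExperiment::assay(nm, "logcounts") else nm
  groups <- as.character(groups)
  if (length(groups) != ncol(nm)) stop("one group label per cell required")
  lev <- unique(groups)
  if (length(lev) != 2) stop("exactly two groups required")
  n1 <- sum(groups == lev[1]); n2 <- sum(groups == lev[2])
  if (min(n1, n2) < 3) stop("each group needs at least 3 cells")
  g1 <- groups == lev[1]
  n <- n1 + n2
  mu <- n1 * n2 / 2
  dn <- as.matrix(nm)
  p <- apply(dn, 1L, function(x) {
    r <- rank(x)
    # rank-sum of group 1, shifted to the Mann-Whitney U scale
    U <- sum(r[g1]) - n1 * (n1 + 1) / 2
    ties <- table(x)
    sigma2 <- (n1 * n2 / 12) *
      ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(1)
    d <- U - mu
    z <- (d - sign(d) * 0.5) / sqrt(sigma2)
    min(1, 2 * stats::pnorm(-abs(z)))
  })
  names(p) <- rownames(nm)
  p
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment of raw p-values, returned in input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in (0, 1\], same order and names as input.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03))
#' @export
bhAdjust <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-gene log2 fold change on de-logged means
#'
#' Means are taken on the de-logged scale (`exp(x) - 1`, inverting the
#' log-normalization) with a pseudocount:
#' `log2((meanTreated + pc) / (meanControl + pc))`.
#'
#' @param nm Normalized genes-by-cells matrix (or `SummarizedExperiment`).
#' @param groups Two-level label per cell.
#' @param treated,control Which label is the treated (numerator) and
#'   control (denominator) group; default the second and first level
#'   encountered.
#' @param pseudocount Added to both means (default 1).
#' @return Named numeric vector of log2 fold changes.
#' @export
log2FoldChange <- function(nm, groups, treated = NULL, control = NULL,
                           pseudocount = 1) {
  nm <- if (is(nm, "SummarizedExperiment"))
    SummarizedExperiment::assay(nm, "logcounts") else nm
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2) stop("exactly two groups required")
  if (is.null(control)) control <- lev[1]
  if (is.null(treated)) treated <- setdiff(lev, control)[1]
  if (!all(c(treated, control) %in% lev)) stop("unknown group label")
  mT <- Matrix::rowMeans(expm1(nm[, groups == treated, drop = FALSE]))
  mC <- Matrix::rowMeans(expm1(nm[, groups == control, drop = FALSE]))
  lfc <- log2((mT + pseudocount) / (mC + pseudocount))
  names(lfc) <- rownames(nm)
  lfc
}

#' Signed significance score
#'
#' `-log10(max(padj, pFloor)) * sign(log2FC)`; the score used to rank
#' genes and compare signatures across experiments.
#'
#' @param padj Adjusted p-values in (0, 1\].
#' @param log2fc Log2 fold changes (sign(0) contributes 0).
#' @param pFloor Floor keeping scores finite (default 1e-300).
#' @return Numeric vector of signed scores.
#' @export
signedSignificance <- function(padj, log2fc, pFloor = 1e-300) {
  if (any(padj <= 0) || any(padj > 1)) stop("padj must lie in (0, 1]")
  -log10(pmax(padj, pFloor)) * sign(log2fc)
}

#' Build a differential-expression signature
#'
#' Convenience wrapper combining [wilcoxonDE()], [bhAdjust()],
#' [log2FoldChange()] and [signedSignificance()] into one table.
#'
#' @inheritParams log2FoldChange
#' @param pFloor See [signedSignificance()].
#' @return `data.frame(gene, log2fc, pval, padj, signedScore)`.
#' @export
deSignature <- function(nm, groups, treated = NULL, control = NULL,
                        pseudocount = 1, pFloor = 1e-300) {
  p <- wilcoxonDE(nm, groups)
  padj <- bhAdjust(p)
  lfc <- log2FoldChange(nm, groups, treated = treated, control = control,
                        pseudocount = pseudocount)
  data.frame(gene = names(p), log2fc = as.numeric(lfc),
             pval = as.numeric(p), padj = as.numeric(padj),
             signedScore = signedSignificance(padj, lfc, pFloor),
             row.names = NULL)
}

#' Count significant genes in a signature
#'
#' @param sig Signature `data.frame` with columns `padj` and `log2fc`.
#' @param padjMax Adjusted-p threshold (default 0.01).
#' @param lfcMin Strict absolute log2 fold-change threshold (default 1).
#' @param nDetected Number of detected genes the fraction refers to
#'   (default `nrow(sig)`).
#' @return List with `nUp`, `nDown`, `nTotal` and `fractionOfDetected`
#'   (percent of detected genes).
#' @examples
#' sig <- data.frame(gene = c("a", "b"), padj = c(0.001, 0.5),
#'                   log2fc = c(2, -3))
#' deSummary(sig)
#' @export
deSummary <- function(sig, padjMax = 0.01, lfcMin = 1,
                      nDetected = nrow(sig)) {
  stopifnot(padjMax > 0, lfcMin > 0)
  nUp <- sum(sig$padj <= padjMax & sig$log2fc > lfcMin)
  nDown <- sum(sig$padj <= padjMax & sig$log2fc < -lfcMin)
  nTotal <- nUp + nDown
  frac <- if (nDetected > 0) 100 * nTotal / nDetected else 0
  list(nUp = nUp, nDown = nDown, nTotal = nTotal,
       fractionOfDetected = frac)
}
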