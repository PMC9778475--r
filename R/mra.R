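# Analytic regulon enrichment (master-regulator analysis): a
# likelihood-weighted, mode-signed cumulation of per-gene z-scores into a
# TF-level normalized enrichment score, two-network consensus, and
# per-cell TF-activity projection.

#' Rank-transform a signature to normal z-scores
#'
#' Per-gene signed scores are converted to mid-rank quantiles
#' `(rank - 0.5) / N` and mapped through the standard normal inverse; the
#' transform is order-preserving and robust to p-value flooring.
#'
#' @param sig Either a signature `data.frame` (columns `gene`,
#'   `signedScore`, as from [deSignature()]) or a named numeric vector of
#'   per-gene scores.
#' @return Named numeric vector of z-scores.
#' @examples
#' z <- signatureToZ(c(a = 1, b = 5, c = -2))
#' @export
signatureToZ <- function(sig) {
  if (is.data.frame(sig)) {
    x <- sig$signedScore
    names(x) <- sig$gene
  } else x <- sig
  if (is.null(names(x))) stop("signature must be named by gene")
  r <- rank(x, ties.method = "average")
  z <- stats::qnorm((r - 0.5) / length(x))
  names(z) <- names(x)
  z
}

#' Regulon normalized enrichment score
#'
#' `NES = sum(mor_i * likelihood_i * z_i) / sqrt(sum(likelihood_i^2))`
#' over the regulon targets present in the signature; under the null
#' (independent standard-normal z, |mor| = 1) the NES is standard normal,
#' so a two-sided normal p-value accompanies it.
#'
#' @param z Named per-gene z-scores (from [signatureToZ()]).
#' @param reg A [Regulon-class].
#' @return List with `nes`, `pval`, `nTargets` (usable targets).
#' @examples
#' r <- regulon("tf", c("a", "b", "c", "d"))
#' regulonNES(c(a = 2, b = 2, c = 2, d = 2), r)$nes  # 4
#' @export
regulonNES <- function(z, reg) {
  stopifnot(is(reg, "Regulon"))
  tg <- regulonTargets(reg)
  keep <- tg$target %in% names(z)
  if (sum(keep) < 2)
    stop("regulon for ", regulonTF(reg),
         " has fewer than 2 targets in the signature")
  tg <- tg[keep, , drop = FALSE]
  zi <- z[tg$target]
  nes <- sum(tg$mor * tg$likelihood * zi) / sqrt(sum(tg$likelihood^2))
  list(nes = as.numeric(nes),
       pval = min(1, 2 * stats::pnorm(-abs(nes))),
       nTargets = nrow(tg))
}

#' Master-regulator analysis of a differential-expression signature
#'
#' Scores every regulon of a network against the signature via
#' [regulonNES()]; activity p-values are BH-adjusted across TFs. The "Exp"
#' column reports the TF's own signed significance score and its rank in
#' the transcriptome-wide differential-expression ordering (1 = most
#' extreme). TFs with fewer than 2 usable targets are skipped with a
#' message.
#'
#' @param sig Signature `data.frame` (from [deSignature()]) or named
#'   signed-score vector covering >= 100 genes.
#' @param network A [RegulonNetwork-class].
#' @param networkName Label stored in the result (default "network").
#' @return An [MRAResult-class], rows ordered by NES (most repressed
#'   first).
#' @export
mra <- function(sig, network, networkName = "network") {
  stopifnot(is(network, "RegulonNetwork"))
  if (length(network) == 0) stop("empty network")
  scores <- if (is.data.frame(sig)) {
    x <- sig$signedScore; names(x) <- sig$gene; x
  } else sig
  if (length(scores) < 100)
    warning("signature covers fewer than 100 genes; ",
            "z-scores will be coarse")
  z <- signatureToZ(scores)
  expRank <- rank(-abs(scores), ties.method = "min")
  rows <- list()
  for (tf in names(network)) {
    res <- tryCatch(regulonNES(z, network[[tf]]), error = function(e) NULL)
    if (is.null(res)) {
      message("skipping TF ", tf, ": fewer than 2 usable targets")
      next
    }
    rows[[tf]] <- data.frame(
      tf = tf, size = res$nTargets, nes = res$nes, pval = res$pval,
      expScore = if (tf %in% names(scores))
        as.numeric(scores[tf]) else NA_real_,
      expRank = if (tf %in% names(scores))
        as.integer(expRank[tf]) else NA_integer_)
  }
  if (!length(rows)) stop("no TF has >= 2 usable targets in the signature")
  tb <- do.call(rbind, rows)
  tb$padj <- bhAdjust(tb$pval)
  tb <- tb[order(tb$nes), c("tf", "size", "nes", "pval", "padj",
                            "expScore", "expRank")]
  rownames(tb) <- NULL
  new("MRAResult", table = tb, network = networkName)
}

#' Two-network consensus of master-regulator analyses
#'
#' Combines the activity NES of the TFs shared by two analyses with an
#' equal-weight Stouffer sum, `(NES_a + NES_b) / sqrt(2)`, and returns
#' both inputs alongside for scatter-style comparison.
#'
#' @param a,b [MRAResult-class] objects with a non-empty TF intersection.
#' @return `data.frame(tf, nesA, nesB, nesCombined, pval)`, ordered by
#'   decreasing |combined NES|; `pval` is the two-sided normal p of the
#'   combined score.
#' @export
mraConsensus <- function(a, b) {
  ta <- mraTable(a); tb <- mraTable(b)
  shared <- intersect(ta$tf, tb$tf)
  if (!length(shared)) stop("no TFs shared between the two analyses")
  nesA <- ta$nes[match(shared, ta$tf)]
  nesB <- tb$nes[match(shared, tb$tf)]
  comb <- (nesA + nesB) / sqrt(2)
  out <- data.frame(tf = shared, nesA = nesA, nesB = nesB,
                    nesCombined = comb,
                    pval = pmin(1, 2 * stats::pnorm(-abs(comb))))
  out[order(-abs(out$nesCombined), out$tf), , drop = FALSE]
}

#' Per-cell TF activity (cells x TFs NES matrix)
#'
#' Applies [signatureToZ()] and [regulonNES()] to every cell of a
#' per-cell signature matrix. All-zero signatures yield NES 0 for every
#' TF; TFs with fewer than 2 usable targets are dropped.
#'
#' @param signatures Genes x cells matrix (from [perCellSignatures()]).
#' @param network A [RegulonNetwork-class].
#' @return Cells x TFs numeric matrix of NES values.
#' @export
perCellTFActivity <- function(signatures, network) {
  stopifnot(is(network, "RegulonNetwork"))
  usable <- names(network)[vapply(as.list(network), function(r)
    sum(regulonTargets(r)$target %in% rownames(signatures)) >= 2,
    logical(1))]
  if (!length(usable)) stop("no TF has >= 2 usable targets")
  out <- matrix(0, ncol(signatures), length(usable),
                dimnames = list(colnames(signatures), usable))
  for (ci in seq_len(ncol(signatures))) {
    s <- signatures[, ci]
    names(s) <- rownames(signatures)
    if (all(s == 0)) next
    z <- signatureToZ(s)
    for (tf in usable)
      out[ci, tf] <- regulonNES(z, network[[tf]])$nes
  }
  out
}
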