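#' @import methods
#' @importFrom S4Vectors SimpleList metadata
NULL

#' Regulon: a transcription factor with a weighted, signed target list
#'
#' A regulon is the set of transcriptional targets of one transcription
#' factor (TF). Each target carries a mode of regulation (`mor`, sign of the
#' TF-target interaction, in \[-1, 1\]) and a `likelihood` (confidence weight
#' in (0, 1\]). Regulons are the unit of master-regulator analysis: the
#' coordinated differential expression of a regulon's targets is evidence
#' for a change in the activity of its TF.
#'
#' @slot tf Character scalar, the TF gene identifier.
#' @slot targets A `data.frame` with columns `target` (character), `mor`
#'   (numeric in \[-1, 1\]) and `likelihood` (numeric in (0, 1\]).
#'
#' @seealso [regulon()] for the user-facing constructor,
#'   [RegulonNetwork-class] for collections.
#' @export
setClass("Regulon",
  representation(tf = "character", targets = "data.frame")
)

setValidity("Regulon", function(object) {
  msg <- character()
  if (length(object@tf) != 1L || is.na(object@tf) || !nzchar(object@tf))
    msg <- c(msg, "'tf' must be a single non-empty gene identifier")
  tg <- object@targets
  if (!all(c("target", "mor", "likelihood") %in% names(tg)))
    msg <- c(msg, "'targets' needs columns target, mor, likelihood")
  else {
    if (nrow(tg) < 2L)
      msg <- c(msg, "a regulon needs at least 2 targets")
    if (anyDuplicated(tg$target))
      msg <- c(msg, "duplicate target genes")
    if (length(object@tf) == 1L && object@tf %in% tg$target)
      msg <- c(msg, "a TF may not be a target of its own regulon")
    if (!all(is.finite(tg$mor)) || any(tg$mor < -1 | tg$mor > 1))
      msg <- c(msg, "'mor' must lie in [-1, 1]")
    if (!all(is.finite(tg$likelihood)) ||
        any(tg$likelihood <= 0 | tg$likelihood > 1))
      msg <- c(msg, "'likelihood' must lie in (0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Regulon
#'
#' @param tf TF gene identifier.
#' @param target Character vector of target gene identifiers.
#' @param mor Numeric vector of modes of regulation in \[-1, 1\]
#'   (+1 activation, -1 repression); recycled.
#' @param likelihood Numeric vector of confidence weights in (0, 1\];
#'   recycled.
#' @return A [Regulon-class] object.
#' @examples
#' regulon("TF1", c("g1", "g2", "g3"), mor = c(1, 1, -1))
#' @export
regulon <- function(tf, target, mor = 1, likelihood = 1) {
  tg <- data.frame(
    target = as.character(target),
    mor = rep_len(as.numeric(mor), length(target)),
    likelihood = rep_len(as.numeric(likelihood), length(target)),
    stringsAsFactors = FALSE
  )
  new("Regulon", tf = as.character(tf), targets = tg)
}

#' @describeIn Regulon-class number of targets
#' @param x A `Regulon`.
#' @export
setMethod("length", "Regulon", function(x) nrow(x@targets))

setMethod("show", "Regulon", function(object) {
  cat("Regulon for TF", object@tf, "with", nrow(object@targets),
      "targets\n")
  cat("  activating:", sum(object@targets$mor > 0),
      " repressing:", sum(object@targets$mor < 0), "\n")
})

#' Accessors for Regulon objects
#'
#' @param object A [Regulon-class].
#' @return `regulonTF` returns the TF identifier; `regulonTargets` the
#'   target `data.frame` (columns `target`, `mor`, `likelihood`).
#' @export
setGeneric("regulonTF", function(object) standardGeneric("regulonTF"))

#' @rdname regulonTF
#' @export
setMethod("regulonTF", "Regulon", function(object) object@tf)

#' @rdname regulonTF
#' @export
setGeneric("regulonTargets", function(object) standardGeneric("regulonTargets"))

#' @rdname regulonTF
#' @export
setMethod("regulonTargets", "Regulon", function(object) object@targets)

#' RegulonNetwork: a collection of regulons
#'
#' A named list of [Regulon-class] objects, one per TF, as inferred from a
#' patient cohort or generated synthetically. Element names are TF
#' identifiers.
#'
#' @seealso [regulonNetwork()], [readRegulons()], [generateNetwork()]
#' @export
setClass("RegulonNetwork", contains = "SimpleList",
         prototype = prototype(elementType = "Regulon"))

setValidity("RegulonNetwork", function(object) {
  if (length(object) == 0L)
    return("a network needs at least one regulon")
  ok <- vapply(object, function(r) is(r, "Regulon"), logical(1))
  if (!all(ok)) return("all elements must be Regulon objects")
  tfs <- vapply(object, regulonTF, character(1))
  if (is.null(names(object)) || !identical(unname(tfs), names(object)))
    return("element names must equal the regulons' TF identifiers")
  if (anyDuplicated(tfs)) return("duplicate TFs in network")
  TRUE
})

#' Construct a RegulonNetwork from a list of regulons
#'
#' @param regulons A list of [Regulon-class] objects.
#' @return A [RegulonNetwork-class], named by TF.
#' @export
regulonNetwork <- function(regulons) {
  tfs <- vapply(regulons, regulonTF, character(1))
  names(regulons) <- tfs
  new("RegulonNetwork", SimpleList(regulons))
}

setMethod("show", "RegulonNetwork", function(object) {
  sizes <- vapply(object, length, integer(1))
  cat("RegulonNetwork of", length(object), "regulons;",
      "targets per TF:", min(sizes), "-", max(sizes), "\n")
  cat("  TFs:", paste(utils::head(names(object), 5), collapse = ", "),
      if (length(object) > 5) "...", "\n")
})

#' MRAResult: master-regulator analysis result
#'
#' One row per scored TF with the regulon activity NES ("Act"), its
#' two-sided normal p-value and BH adjustment, the TF's own
#' differential-expression signed score ("Exp") and the TF's rank in the
#' transcriptome-wide differential-expression ranking.
#'
#' @slot table `data.frame` with columns `tf`, `size`, `nes`, `pval`,
#'   `padj`, `expScore`, `expRank`, ordered by `nes`.
#' @slot network Character scalar naming the network used.
#' @seealso [mra()], [mraConsensus()]
#' @export
setClass("MRAResult",
  representation(table = "data.frame", network = "character")
)

setValidity("MRAResult", function(object) {
  tb <- object@table
  need <- c("tf", "size", "nes", "pval", "padj", "expScore", "expRank")
  if (!all(need %in% names(tb)))
    return(paste("table needs columns:", paste(need, collapse = ", ")))
  if (nrow(tb) && (any(tb$pval <= 0) || any(tb$pval > 1)))
    return("p-values must lie in (0, 1]")
  if (anyDuplicated(tb$tf)) return("one row per TF required")
  TRUE
})

setMethod("show", "MRAResult", function(object) {
  tb <- object@table
  cat("MRAResult (network:", object@network, ") -", nrow(tb),
      "TFs scored\n")
  top <- tb[order(tb$nes), , drop = FALSE]
  cat("Most repressed regulons:\n")
  print(utils::head(top[, c("tf", "nes", "padj", "expScore")], 5),
        row.names = FALSE)
})

#' @describeIn MRAResult-class extract the result table
#' @param x An `MRAResult`.
#' @param row.names,optional,... passed on for S3 compatibility; unused.
#' @export
as.data.frame.MRAResult <- function(x, row.names = NULL, optional = FALSE,
                                    ...) {
  x@table
}

#' @rdname regulonTF
#' @export
setGeneric("mraTable", function(object) standardGeneric("mraTable"))

#' @rdname regulonTF
#' @export
setMethod("mraTable", "MRAResult", function(object) object@table)
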