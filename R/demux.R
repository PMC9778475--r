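#' Assign one cell to a hashtag group
#'
#' Two-hashtag rule for a pooled control/treated design: a cell with zero
#' counts for one hashtag but at least one for the other is assigned to the
#' latter; otherwise it is assigned to a group when that group's hashtag
#' count is at least `ratioThreshold` times the other's; all remaining
#' cells (including those with no hashtag counts at all) are multiplets of
#' ambiguous origin.
#'
#' @param h1 Hashtag-1 (control) count, non-negative integer.
#' @param h2 Hashtag-2 (treated) count, non-negative integer.
#' @param ratioThreshold Ratio required for assignment (> 1; default 10,
#'   applied inclusively: `h1 >= ratioThreshold * h2` assigns `ctr`).
#' @return One of `"ctr"`, `"pnb"`, `"multiplet"`.
#' @examples
#' assignCell(5, 0)    # "ctr"
#' assignCell(2, 20)   # "pnb"
#' assignCell(2, 19)   # "multiplet"
#' @export
assignCell <- function(h1, h2, ratioThreshold = 10) {
  .checkHashtags(h1, h2, ratioThreshold)
  .assignVec(h1, h2, ratioThreshold)
}

.checkHashtags <- function(h1, h2, ratioThreshold) {
  if (any(h1 < 0) || any(h2 < 0)) stop("hashtag counts must be non-negative")
  if (ratioThreshold <= 1) stop("ratioThreshold must exceed 1")
}

.assignVec <- function(h1, h2, t) {
  lab <- rep("multiplet", length(h1))
  lab[h1 == 0 & h2 >= 1] <- "pnb"
  lab[h2 == 0 & h1 >= 1] <- "ctr"
  both <- h1 > 0 & h2 > 0
  lab[both & h1 >= t * h2] <- "ctr"
  lab[both & h2 >= t * h1] <- "pnb"
  lab
}

#' Demultiplex a hashed experiment
#'
#' Applies [assignCell()] to every barcode and tabulates the groups.
#'
#' @param hashtags A `data.frame` (or matrix) with columns `barcode`,
#'   `hashtag1`, `hashtag2` — or a [SingleCellExperiment::SingleCellExperiment]
#'   from [generateDataset()], whose `colData` provides them.
#' @param ratioThreshold See [assignCell()].
#' @return A list with `labels` (named character vector, one of
#'   `ctr`/`pnb`/`multiplet` per barcode) and `summary` (named integer
#'   counts over the three labels, summing to the number of cells).
#' @examples
#' h <- data.frame(barcode = c("a", "b", "c"),
#'                 hashtag1 = c(1, 0, 3), hashtag2 = c(0, 1, 5))
#' demultiplex(h)$summary
#' @export
demultiplex <- function(hashtags, ratioThreshold = 10) {
  if (is(hashtags, "SummarizedExperiment")) {
    cd <- SummarizedExperiment::colData(hashtags)
    hashtags <- data.frame(barcode = rownames(cd),
                           hashtag1 = cd$hashtag1, hashtag2 = cd$hashtag2)
  }
  hashtags <- as.data.frame(hashtags)
  need <- c("barcode", "hashtag1", "hashtag2")
  if (!all(need %in% names(hashtags)))
    stop("hashtags needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(hashtags$barcode)) stop("duplicate barcodes")
  .checkHashtags(hashtags$hashtag1, hashtags$hashtag2, ratioThreshold)
  labels <- .assignVec(hashtags$hashtag1, hashtags$hashtag2, ratioThreshold)
  names(labels) <- hashtags$barcode
  lev <- c("ctr", "pnb", "multiplet")
  summary <- vapply(lev, function(l) sum(labels == l), integer(1))
  list(labels = labels, summary = summary)
}
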