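#' Filter cells by number of detected genes
#'
#' Removes cells with fewer than `minGenes` genes detected (count > 0);
#' column order is preserved. Operates on a genes-by-cells matrix (dense or
#' sparse) or any `SummarizedExperiment` carrying a `counts` assay.
#'
#' @param m Count matrix or `SummarizedExperiment`.
#' @param minGenes Minimum detected genes to retain a cell (default 1000).
#' @return Input with failing cells dropped.
#' @export
setGeneric("filterCells", function(m, minGenes = 1000)
  standardGeneric("filterCells"))

#' @rdname filterCells
#' @export
setMethod("filterCells", "ANY", function(m, minGenes = 1000) {
  stopifnot(minGenes >= 0)
  detected <- Matrix::colSums(.asMatrixLike(m) > 0)
  m[, detected >= minGenes, drop = FALSE]
})

#' Filter genes by number of cells expressing them
#'
#' Retains genes detected (count > 0) in at least `minCells` cells.
#'
#' @param m Count matrix or `SummarizedExperiment`.
#' @param minCells Minimum expressing cells to retain a gene (default 3).
#' @return Input with failing genes dropped.
#' @export
setGeneric("filterGenes", function(m, minCells = 3)
  standardGeneric("filterGenes"))

#' @rdname filterGenes
#' @export
setMethod("filterGenes", "ANY", function(m, minCells = 3) {
  stopifnot(minCells >= 0)
  present <- Matrix::rowSums(.asMatrixLike(m) > 0)
  m[present >= minCells, , drop = FALSE]
})

#' Log-normalize a count matrix
#'
#' Each entry becomes `log(1 + count * scaleFactor / cellTotal)` (natural
#' log), so zeros map to zeros and per-cell totals are equalized to
#' `scaleFactor` before the log.
#'
#' @param m Count matrix (genes x cells) or `SummarizedExperiment`; every
#'   cell must have a positive total count.
#' @param scaleFactor Library-size target (default 10000).
#' @return For matrix input, a sparse normalized matrix; for a
#'   `SummarizedExperiment`, the object with a `logcounts` assay added.
#' @examples
#' m <- matrix(c(100, 9900), 2, 1,
#'             dimnames = list(c("g1", "g2"), "c1"))
#' logNormalize(m)["g1", ]  # log(101)
#' @export
setGeneric("logNormalize", function(m, scaleFactor = 10000)
  standardGeneric("logNormalize"))

.logNormalizeMatrix <- function(m, scaleFactor) {
  tot <- Matrix::colSums(m)
  if (any(tot <= 0))
    stop("zero-total cell(s): ",
         paste(utils::head(colnames(m)[tot <= 0], 5), collapse = ", "))
  sm <- as(as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  # operate on non-zero entries only; zeros stay zero by construction
  cellOf <- rep(seq_len(ncol(sm)), diff(sm@p))
  sm@x <- log1p(sm@x * scaleFactor / tot[cellOf])
  sm
}

#' @rdname logNormalize
#' @export
setMethod("logNormalize", "ANY", function(m, scaleFactor = 10000) {
  if (is(m, "SummarizedExperiment")) {
    lc <- .logNormalizeMatrix(SummarizedExperiment::assay(m, "counts"),
                              scaleFactor)
    SummarizedExperiment::assay(m, "logcounts") <- lc
    m
  } else .logNormalizeMatrix(m, scaleFactor)
})

#' Per-gene mean and dispersion of normalized expression
#'
#' Dispersion is the variance-to-mean ratio of (log-normalized) expression
#' across cells (sample variance, n - 1); genes constant across cells have
#' dispersion 0.
#'
#' @param nm Normalized genes-by-cells matrix (>= 2 cells) or a
#'   `SummarizedExperiment` with a `logcounts` assay.
#' @return `data.frame(gene, mean, variance, dispersion)`.
#' @export
geneStats <- function(nm) {
  nm <- if (is(nm, "SummarizedExperiment"))
    SummarizedExperiment::assay(nm, "logcounts") else nm
  if (ncol(nm) < 2) stop("gene statistics need at least 2 cells")
  mu <- Matrix::rowMeans(nm)
  ex2 <- Matrix::rowMeans(nm^2)
  v <- (ex2 - mu^2) * ncol(nm) / (ncol(nm) - 1)
  v <- pmax(v, 0)
  disp <- ifelse(v == 0, 0, v / mu)
  data.frame(gene = rownames(nm), mean = as.numeric(mu),
             variance = as.numeric(v), dispersion = as.numeric(disp),
             row.names = NULL)
}

#' Pseudobulk aggregation of raw counts by group
#'
#' Sums raw counts over the cells of each group, emulating one bulk RNA-seq
#' profile per group.
#'
#' @param m Raw count matrix (genes x cells) or `SummarizedExperiment`.
#' @param labels Group label per cell (recycled names not used; must align
#'   with columns).
#' @return Genes x groups matrix of summed counts.
#' @export
pseudobulk <- function(m, labels) {
  mm <- .asMatrixLike(m)
  if (length(labels) != ncol(mm))
    stop("one label per cell required")
  if (anyNA(labels)) stop("unknown (NA) label")
  groups <- unique(as.character(labels))
  out <- vapply(groups, function(g)
    Matrix::rowSums(mm[, labels == g, drop = FALSE]),
    numeric(nrow(mm)))
  out <- matrix(out, nrow = nrow(mm),
                dimnames = list(rownames(mm), groups))
  out
}

#' Reads per million
#'
#' Scales per-gene totals so they sum to one million.
#'
#' @param totals Non-negative per-gene counts with a positive sum.
#' @return Numeric vector summing to 1e6.
#' @examples
#' rpm(c(a = 1, b = 9))
#' @export
rpm <- function(totals) {
  if (any(totals < 0)) stop("negative counts")
  s <- sum(totals)
  if (s <= 0) stop("all-zero input: RPM undefined")
  totals * 1e6 / s
}
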