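# Readers and writers for the plain-text formats the pipeline exchanges:
# 10x-style MTX triplets, GMT gene sets, regulon TSVs, hashtag and
# survival CSVs.

#' Read a 10x-style MTX triplet directory
#'
#' Expects `matrix.mtx`, `features.tsv` (gene ids in column 1) and
#' `barcodes.tsv` in `dir`.
#'
#' @param dir Directory holding the three files.
#' @return Sparse genes-by-cells count matrix with dimnames.
#' @export
readCountsMTX <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  feats <- utils::read.table(file.path(dir, "features.tsv"), sep = "\t",
                             header = FALSE, stringsAsFactors = FALSE)
  bcs <- utils::read.table(file.path(dir, "barcodes.tsv"), sep = "\t",
                           header = FALSE, stringsAsFactors = FALSE)
  rownames(m) <- feats[[1]]
  colnames(m) <- bcs[[1]]
  .assertCountMatrix(m)
  as(m, "CsparseMatrix")
}

#' Write a count matrix as a 10x-style MTX triplet
#'
#' @param m Genes-by-cells matrix with dimnames.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCountsMTX <- function(m, dir) {
  .assertCountMatrix(m)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  utils::write.table(data.frame(rownames(m)),
                     file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(colnames(m)),
                     file.path(dir, "barcodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (set name, description, then member genes, tab
#'   separated).
#' @return Named list of character vectors.
#' @export
readGMT <- function(path) fgsea::gmtPathways(path)

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGMT <- function(sets, path) {
  stopifnot(!is.null(names(sets)))
  lines <- vapply(names(sets), function(n)
    paste(c(n, n, sets[[n]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a regulon network from TSV
#'
#' @param path TSV with header columns `tf`, `target`, `mor`, `likelihood`.
#' @return A [RegulonNetwork-class].
#' @export
readRegulons <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("tf", "target", "mor", "likelihood")
  if (!all(need %in% names(df)))
    stop("regulon TSV needs columns: ", paste(need, collapse = ", "))
  regs <- lapply(split(df, df$tf), function(d)
    regulon(d$tf[1], d$target, d$mor, d$likelihood))
  regulonNetwork(unname(regs))
}

#' Write a regulon network to TSV
#'
#' @param network A [RegulonNetwork-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeRegulons <- function(network, path) {
  rows <- lapply(as.list(network), function(r) {
    tg <- regulonTargets(r)
    data.frame(tf = regulonTF(r), target = tg$target, mor = tg$mor,
               likelihood = tg$likelihood)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-cell hashtag counts from CSV
#'
#' @param path CSV with header columns `barcode`, `hashtag1`, `hashtag2`.
#' @return `data.frame` suitable for [demultiplex()].
#' @export
readHashtags <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("barcode", "hashtag1", "hashtag2")
  if (!all(need %in% names(df)))
    stop("hashtag CSV needs columns: ", paste(need, collapse = ", "))
  df
}

#' Read a survival table from CSV
#'
#' @param path CSV with header columns `sample`, `time`, `event`, `expr`.
#' @return `data.frame`.
#' @export
readSurvival <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "time", "event", "expr")
  if (!all(need %in% names(df)))
    stop("survival CSV needs columns: ", paste(need, collapse = ", "))
  df
}
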