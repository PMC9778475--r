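# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG state, restoring the caller's state
# afterwards so that seeded package functions never disturb the session RNG.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-specific child seed from a master seed, kept within the
# 32-bit integer range.
childSeed <- function(seed, stream) {
  (as.integer(seed) * 1009L + as.integer(stream) * 9973L) %% 2147483629L
}

.assertCountMatrix <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("count matrix needs gene rownames and cell barcode colnames")
  if (anyDuplicated(rownames(m))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(m))) stop("duplicate cell barcodes")
  invisible(m)
}

# Extract a plain (possibly sparse) matrix from matrix-like or
# SummarizedExperiment input.
.asMatrixLike <- function(x, assay = "counts") {
  if (is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, assay)
  else x
}
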