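# Independent oracles used to validate the package implementations.
# These are deliberately naive (enumeration / direct formula) and share no
# code with the implementation paths they check.

suppressPackageStartupMessages({
  library(Matrix)
  library(SummarizedExperiment)
})

# Exact two-sided Wilcoxon p by enumeration of all group assignments:
# proportion of assignments whose rank-sum deviates from its mean at least
# as much as observed.
exactWilcoxonP <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n1 <- length(x)
  obs <- sum(r[seq_len(n1)])
  mu <- n1 * (length(pooled) + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  sums <- apply(combos, 2, function(idx) sum(r[idx]))
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-12)
}

# Brute-force BH step-up: q(i) = min_{j >= i} p(j) * n / j on the sorted
# scale, capped at 1, returned in input order.
bruteBH <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    cand <- vapply(i:n, function(j) p[o[j]] * n / j, numeric(1))
    q[o[i]] <- min(1, min(cand))
  }
  q
}

# Brute-force weight-0 GSEA enrichment score: literal running-sum scan;
# a tie between the positive and negative extremum resolves positive,
# matching the documented contract.
bruteES <- function(scores, set) {
  ord <- order(-scores, names(scores))
  genes <- names(scores)[ord]
  hit <- genes %in% set
  k <- sum(hit); N <- length(scores)
  run <- numeric(N); acc <- 0
  for (i in seq_len(N)) {
    acc <- acc + if (hit[i]) 1 / k else -1 / (N - k)
    run[i] <- acc
  }
  hi <- max(run, 0); lo <- min(run, 0)
  if (hi >= -lo - 1e-9) hi else lo
}

# Small dense toy count matrix with dimnames.
toyCounts <- function(mat, genes = NULL, cells = NULL) {
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(mat)))
  if (is.null(cells)) cells <- sprintf("c%d", seq_len(ncol(mat)))
  dimnames(mat) <- list(genes, cells)
  mat
}

# Shared small synthetic experiment for cross-module tests (built once).
smallExperiment <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      net <- generateNetwork(10, 20, genes = geneIds(1000), seed = 7)
      pt <- data.frame(tf = names(net)[1:3], effect = c(-1.2, -1, 1.5))
      cfg <- simConfig(nCellsPerGroup = 80, nGenes = 1000,
                       perturbedTfs = pt, seed = 5)
      cache <<- list(net = net, cfg = cfg,
                     sce = generateDataset(cfg, net))
    }
    cache
  }
})
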