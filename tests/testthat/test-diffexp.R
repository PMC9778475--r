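test_that("Wilcoxon p matches the normal approximation and its oracles", {
  m <- toyCounts(matrix(c(1, 2, 3, 4, 5, 6), nrow = 1))
  g <- c("a", "a", "a", "b", "b", "b")
  p <- wilcoxonDE(m, g)
  expect_equal(unname(p), 0.0809, tolerance = 1e-3)
  # exact-enumeration oracle on the same data
  expect_equal(exactWilcoxonP(1:3, 4:6), 0.1)
  expect_lte(abs(unname(p) - 0.1), 0.03)

  tied <- toyCounts(matrix(rep(2, 6), nrow = 1))
  expect_equal(unname(wilcoxonDE(tied, g)), 1)

  perm <- sample(6)
  expect_equal(wilcoxonDE(m[, perm, drop = FALSE], g[perm]), p)

  expect_error(wilcoxonDE(m, c("a", "a", "b", "b", "b", "b")), "3 cells")
})

test_that("Wilcoxon agrees with stats::wilcox.test across random matrices", {
  set.seed(9)
  m <- toyCounts(matrix(rpois(50 * 12, 3), nrow = 50))
  g <- rep(c("x", "y"), each = 6)
  p <- wilcoxonDE(m, g)
  ref <- apply(m, 1, function(r)
    suppressWarnings(stats::wilcox.test(r[g == "x"], r[g == "y"],
                                        exact = FALSE,
                                        correct = TRUE))$p.value)
  expect_equal(unname(p), unname(ref), tolerance = 1e-10)
})

test_that("Wilcoxon normal approximation tracks exact enumeration", {
  set.seed(2)
  for (n1 in 4:6) for (rep in 1:3) {
    x <- rnorm(n1); y <- rnorm(n1) + rnorm(1)
    m <- toyCounts(matrix(c(x, y), nrow = 1))
    p <- unname(wilcoxonDE(m, rep(c("a", "b"), each = n1)))
    expect_lte(abs(p - exactWilcoxonP(x, y)), 0.03)
  }
})

test_that("BH adjustment reproduces the step-up formula", {
  expect_equal(bhAdjust(0.2), 0.2)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(c(0.001, 0.5)), c(0.002, 0.5))
  expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
  expect_error(bhAdjust(c(-0.1)), "0, 1")

  set.seed(3)
  for (i in 1:20) {
    p <- runif(sample(2:30, 1))
    expect_equal(bhAdjust(p), bruteBH(p), tolerance = 1e-12)
  }
})

test_that("log2 fold change uses de-logged means with pseudocount", {
  # treated cells at expm1 = 3, control at expm1 = 1
  m <- toyCounts(matrix(c(log(2), log(2), log(4), log(4)), nrow = 1))
  g <- c("ctr", "ctr", "pnb", "pnb")
  lfc <- log2FoldChange(m, g, treated = "pnb", control = "ctr")
  expect_equal(unname(lfc), 1)
  # antisymmetry under label swap
  rev <- log2FoldChange(m, g, treated = "ctr", control = "pnb")
  expect_equal(unname(rev), -1)
  # identical groups -> 0
  same <- toyCounts(matrix(rep(log(3), 4), nrow = 1))
  expect_equal(unname(log2FoldChange(same, g)), 0)
})

test_that("signed significance combines adjusted p and fold-change sign", {
  expect_equal(signedSignificance(0.01, -2), -2)
  expect_equal(signedSignificance(1, 5), 0)
  expect_equal(signedSignificance(0.1, 0), 0)
  # p floor keeps scores finite
  expect_equal(signedSignificance(1e-310, 1), 300)
  expect_error(signedSignificance(0, 1), "0, 1")
})

test_that("signature summary counts thresholded genes symmetrically", {
  sig <- data.frame(gene = sprintf("g%d", 1:6),
                    padj = c(0.001, 0.01, 0.02, 0.001, 0.5, 0.009),
                    log2fc = c(2, 1.5, 3, -1.2, -4, 1))
  s <- deSummary(sig)
  expect_equal(s$nUp, 2)      # g1, g2 (g3 fails padj, g6 fails lfc > 1)
  expect_equal(s$nDown, 1)    # g4
  expect_equal(s$nTotal, s$nUp + s$nDown)
  expect_equal(s$fractionOfDetected, 100 * 3 / 6)

  none <- deSummary(sig[0, ])
  expect_equal(unlist(none), c(nUp = 0, nDown = 0, nTotal = 0,
                               fractionOfDetected = 0))
})

test_that("null data yield a calibrated signature", {
  exp0 <- simConfig(nCellsPerGroup = 80, nGenes = 600, multipletRate = 0,
                    seed = 13)
  sce <- generateDataset(exp0)
  nm <- logNormalize(filterGenes(assay(sce, "counts"), 3))
  sig <- deSignature(nm, sce$trueGroup, treated = "pnb", control = "ctr")
  expect_true(all(sig$padj >= sig$pval - 1e-12))
  expect_lte(100 * mean(sig$padj <= 0.01), 1.5)
})
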