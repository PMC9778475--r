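test_that("rank-based z transform hits its closed-form quantiles", {
  x <- rnorm(100)
  names(x) <- sprintf("g%03d", 1:100)
  z <- signatureToZ(x)
  expect_equal(unname(z[which.max(x)]), qnorm(0.995), tolerance = 1e-12)
  expect_equal(unname(z[which.min(x)]), qnorm(0.005), tolerance = 1e-12)
  expect_equal(median(z), 0, tolerance = 1e-9)
  # order preserving
  expect_equal(order(z), order(x))
})

test_that("regulon NES follows the weighted Stouffer formula", {
  r <- regulon("tf", c("a", "b", "c", "d"), mor = 1, likelihood = 1)
  z <- c(a = 2, b = 2, c = 2, d = 2)
  expect_equal(regulonNES(z, r)$nes, 4)
  expect_equal(regulonNES(c(a = 0, b = 0, c = 0, d = 0), r)$nes, 0)
  # flipping modes negates the NES
  rneg <- regulon("tf", c("a", "b", "c", "d"), mor = -1)
  expect_equal(regulonNES(z, rneg)$nes, -4)
  # uniform doubling of likelihoods leaves NES unchanged
  rHalf <- regulon("tf", c("a", "b", "c", "d"), likelihood = 0.25)
  rFull <- regulon("tf", c("a", "b", "c", "d"), likelihood = 0.5)
  zr <- c(a = 1.2, b = -0.4, c = 0.8, d = 2)
  expect_equal(regulonNES(zr, rHalf)$nes, regulonNES(zr, rFull)$nes)
  # non-uniform case against the direct formula
  rw <- regulon("tf", c("a", "b", "c"), mor = c(1, -1, 1),
                likelihood = c(0.9, 0.5, 0.2))
  zw <- c(a = 1.1, b = -2.3, c = 0.4)
  manual <- sum(c(1, -1, 1) * c(0.9, 0.5, 0.2) * zw) /
    sqrt(sum(c(0.9, 0.5, 0.2)^2))
  expect_equal(regulonNES(zw, rw)$nes, manual)
  # fewer than 2 usable targets is an error
  expect_error(regulonNES(c(a = 1, x = 2), r), "fewer than 2")
})

test_that("regulon NES is standard normal under the null", {
  set.seed(31)
  r <- regulon("tf", sprintf("t%02d", 1:20), mor = 1, likelihood = 1)
  nes <- vapply(1:500, function(i) {
    z <- rnorm(20); names(z) <- sprintf("t%02d", 1:20)
    regulonNES(z, r)$nes
  }, numeric(1))
  expect_gt(sd(nes), 0.9)
  expect_lt(sd(nes), 1.1)
  expect_lt(abs(mean(nes)), 0.15)
})

test_that("mra scores, adjusts and ranks TFs against the signature", {
  exp <- smallExperiment()
  sce <- exp$sce[, !exp$sce$trueMultiplet]
  nm <- logNormalize(filterGenes(assay(sce, "counts"), 3))
  sig <- deSignature(nm, sce$trueGroup, treated = "pnb", control = "ctr")
  res <- mra(sig, exp$net)
  tb <- mraTable(res)
  expect_s4_class(res, "MRAResult")
  expect_true(all(tb$pval > 0 & tb$pval <= 1))
  expect_true(all(tb$padj >= tb$pval - 1e-12))
  expect_false(is.unsorted(tb$nes))

  planted <- exp$cfg@perturbedTfs
  downTfs <- planted$tf[planted$effect < 0]
  top <- tb$tf[order(-abs(tb$nes))][seq_len(3)]
  expect_true(all(downTfs %in% top))
  expect_true(all(tb$nes[match(downTfs, tb$tf)] < 0))

  # negating the signature negates every NES
  sigNeg <- sig
  sigNeg$signedScore <- -sig$signedScore
  tbNeg <- mraTable(mra(sigNeg, exp$net))
  expect_equal(tbNeg$nes[match(tb$tf, tbNeg$tf)], -tb$nes,
               tolerance = 1e-9)

  # single-regulon network gives a single row
  one <- mra(sig, regulonNetwork(list(exp$net[[1]])))
  expect_equal(nrow(mraTable(one)), 1)
})

test_that("a shuffled signature destroys the planted enrichment", {
  exp <- smallExperiment()
  sce <- exp$sce[, !exp$sce$trueMultiplet]
  nm <- logNormalize(filterGenes(assay(sce, "counts"), 3))
  sig <- deSignature(nm, sce$trueGroup, treated = "pnb", control = "ctr")
  tf <- exp$cfg@perturbedTfs$tf[1]
  obs <- abs(mraTable(mra(sig, exp$net))$nes)
  obsTf <- obs[match(tf, mraTable(mra(sig, exp$net))$tf)]
  set.seed(77)
  shuffled <- vapply(1:40, function(i) {
    s2 <- sig
    s2$gene <- sample(s2$gene)
    abs(regulonNES(signatureToZ(s2), exp$net[[tf]])$nes)
  }, numeric(1))
  expect_gt(obsTf, quantile(shuffled, 0.95))
})

test_that("consensus combines shared TFs by equal-weight Stouffer", {
  mk <- function(tfs, nes) new("MRAResult", network = "x", table =
    data.frame(tf = tfs, size = 5L, nes = nes, pval = 0.5, padj = 0.5,
               expScore = 0, expRank = 1L))
  a <- mk(c("t1", "t2", "t3"), c(2, 2, 1))
  b <- mk(c("t2", "t3", "t4"), c(2, -2, 5))
  cons <- mraConsensus(a, b)
  expect_setequal(cons$tf, c("t2", "t3"))
  expect_equal(cons$nesCombined[cons$tf == "t2"], 2 * sqrt(2))
  expect_equal(cons$nesCombined[cons$tf == "t3"], (1 - 2) / sqrt(2))
  # self-consensus scales by sqrt(2)
  self <- mraConsensus(a, a)
  expect_equal(self$nesCombined[match("t1", self$tf)], sqrt(2) * 2)
  expect_error(mraConsensus(a, mk("zz", 1)), "shared")
})

test_that("per-cell TF activity separates treated and control cells", {
  exp <- smallExperiment()
  sce <- exp$sce[, !exp$sce$trueMultiplet]
  nm <- logNormalize(filterGenes(assay(sce, "counts"), 3))
  sub <- c(which(sce$trueGroup == "ctr")[1:20],
           which(sce$trueGroup == "pnb")[1:20])
  sigs <- perCellSignatures(nm)[, sub]
  act <- perCellTFActivity(sigs, exp$net)
  expect_equal(nrow(act), 40)
  expect_equal(ncol(act), length(exp$net))
  grp <- sce$trueGroup[sub]
  downTf <- exp$cfg@perturbedTfs$tf[exp$cfg@perturbedTfs$effect < 0][1]
  expect_lt(mean(act[grp == "pnb", downTf]),
            mean(act[grp == "ctr", downTf]))
  # an all-zero signature projects to zero activity
  zeroSig <- sigs[, 1, drop = FALSE]; zeroSig[] <- 0
  act0 <- perCellTFActivity(zeroSig, exp$net)
  expect_true(all(act0 == 0))
})
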