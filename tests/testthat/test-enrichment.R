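test_that("enrichment score matches hand-enumerated running sums", {
  s <- c(a = 4, b = 3, c = 2, d = 1)
  # single-gene set ranked first
  one <- gseaES(s, "a")
  expect_equal(one$es, 1)
  # N = 4, set at ranks {1, 2}, weight 0
  two <- gseaES(s, c("a", "b"), weight = 0)
  expect_equal(unname(two$running), c(0.5, 1.0, 0.5, 0.0))
  expect_equal(two$es, 1)
  expect_setequal(two$leadingEdge, c("a", "b"))
  # negating scores flips the sign for weight 0
  neg <- gseaES(-s, c("a", "b"), weight = 0)
  expect_equal(neg$es, -1)

  expect_error(gseaES(s, c("x", "y")), "intersect")
  expect_error(gseaES(s, names(s)), "universe")
})

test_that("weight-0 ES matches the brute-force oracle on random cases", {
  set.seed(5)
  for (N in c(6, 12, 20)) {
    scores <- rnorm(N)
    names(scores) <- sprintf("g%02d", seq_len(N))
    for (k in 1:5) {
      for (rep in 1:10) {
        set <- sample(names(scores), k)
        expect_equal(gseaES(scores, set, weight = 0)$es,
                     bruteES(scores, set), tolerance = 1e-12)
      }
    }
  }
})

test_that("|ES| never exceeds 1 and weighting respects score magnitudes", {
  set.seed(6)
  for (rep in 1:25) {
    scores <- rnorm(30); names(scores) <- sprintf("g%02d", 1:30)
    set <- sample(names(scores), sample(2:8, 1))
    for (w in c(0, 1, 2))
      expect_lte(abs(gseaES(scores, set, weight = w)$es), 1 + 1e-12)
  }
})

test_that("NES estimation is deterministic, signed and never reports p = 0", {
  set.seed(8)
  scores <- rnorm(1000); names(scores) <- sprintf("g%04d", 1:1000)
  top <- names(sort(scores, decreasing = TRUE))[1:20]
  r1 <- gseaNES(scores, top, nPerm = 200, seed = 3)
  r2 <- gseaNES(scores, top, nPerm = 200, seed = 3)
  expect_identical(r1$nes, r2$nes)
  expect_gt(r1$nes, 0)
  expect_lte(r1$pval, 0.01)
  expect_gt(r1$pval, 0)
  expect_equal(sign(r1$nes), sign(r1$es))

  bottom <- names(sort(scores))[1:20]
  rneg <- gseaNES(scores, bottom, nPerm = 200, seed = 3)
  expect_lt(rneg$nes, 0)
  expect_error(gseaNES(scores, top, nPerm = 50), ">= 100")
})

test_that("permutation p is approximately uniform under the null", {
  set.seed(12)
  scores <- rnorm(300); names(scores) <- sprintf("g%03d", 1:300)
  ps <- vapply(1:200, function(i) {
    set <- sample(names(scores), 15)
    gseaNES(scores, set, nPerm = 100, seed = i)$pval
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("per-cell signatures are centered against the dataset mean", {
  exp <- smallExperiment()
  nm <- logNormalize(assay(exp$sce, "counts")[, 1:30])
  sigs <- perCellSignatures(nm)
  expect_equal(dim(sigs), dim(nm))
  expect_equal(max(abs(rowSums(sigs))), 0, tolerance = 1e-9)
  # a cell equal to the dataset mean profile scores zero everywhere
  mcell <- cbind(nm[, 1:2], meanCell = Matrix::rowMeans(nm[, 1:2]))
  s3 <- perCellSignatures(mcell)
  expect_true(all(abs(s3[, "meanCell"]) <
                  abs(s3[, 1]) + abs(s3[, 2]) + 1e-9))
})

test_that("per-cell enrichment flags a constructed pathway overexpression", {
  set.seed(14)
  base <- matrix(rnorm(200 * 10, 2, 0.3), 200, 10,
                 dimnames = list(sprintf("g%03d", 1:200),
                                 sprintf("c%02d", 1:10)))
  pathway <- sprintf("g%03d", 1:15)
  other <- sprintf("g%03d", 101:115)
  base[pathway, "c01"] <- base[pathway, "c01"] + 2
  sigs <- perCellSignatures(base)
  nes <- perCellEnrichment(sigs, list(path = pathway, other = other),
                           nPerm = 200, seed = 4)
  expect_equal(dim(nes), c(10L, 2L))
  expect_gt(nes["c01", "path"], nes["c01", "other"])
  expect_gt(nes["c01", "path"], max(nes[-1, "path"]))

  # all-zero signature row yields NES 0 by convention
  zero <- sigs; zero[, "c02"] <- 0
  nes0 <- perCellEnrichment(zero[, "c02", drop = FALSE],
                            list(path = pathway), nPerm = 100, seed = 1)
  expect_equal(unname(nes0[1, 1]), 0)
})

test_that("treated cells show elevated NES for an up-shifted program", {
  exp <- smallExperiment()
  upTf <- exp$cfg@perturbedTfs$tf[exp$cfg@perturbedTfs$effect > 0][1]
  tg <- regulonTargets(exp$net[[upTf]])
  set <- tg$target[tg$mor > 0]
  sce <- exp$sce[, !exp$sce$trueMultiplet]
  nm <- logNormalize(filterGenes(assay(sce, "counts"), 3))
  sub <- c(which(sce$trueGroup == "ctr")[1:15],
           which(sce$trueGroup == "pnb")[1:15])
  sigs <- perCellSignatures(nm)[, sub]
  nes <- perCellEnrichment(sigs, list(up = set), nPerm = 150, seed = 9)
  grp <- sce$trueGroup[sub]
  expect_gt(mean(nes[grp == "pnb", "up"]), mean(nes[grp == "ctr", "up"]))
})
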