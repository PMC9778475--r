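test_that("Kaplan-Meier steps match the hand product-limit", {
  d <- data.frame(time = c(1, 2, 3, 4), event = c(1, 1, 1, 1))
  km <- kmEstimate(d)
  expect_equal(km$survival, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$nRisk, 4:1)
  expect_false(is.unsorted(rev(km$survival)))

  # all censored: no steps, S stays at 1
  cens <- data.frame(time = 1:4, event = rep(0, 4))
  expect_equal(nrow(kmEstimate(cens)), 0)

  # moving a censoring time beyond the last event leaves steps unchanged
  d2 <- rbind(d, data.frame(time = 10, event = 0))
  d3 <- rbind(d, data.frame(time = 99, event = 0))
  expect_equal(kmEstimate(d2), kmEstimate(d3))
  expect_equal(kmEstimate(d2)$survival, c(0.8, 0.6, 0.4, 0.2))
  expect_error(kmEstimate(data.frame(time = c(0, 1), event = c(1, 1))),
               "non-positive")
})

test_that("Kaplan-Meier matches survival::survfit on every 4-subject pattern", {
  times <- c(1, 2, 3, 4)
  for (code in 0:15) {
    ev <- as.integer(intToBits(code)[1:4])
    d <- data.frame(time = times, event = ev)
    km <- kmEstimate(d)
    if (nrow(km) == 0) {
      expect_equal(sum(ev), 0)
      next
    }
    sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = d)
    at <- summary(sf, times = km$time)
    expect_equal(km$survival, at$surv, tolerance = 1e-12,
                 info = paste("pattern", code))
  }
  # tied event times
  dt <- data.frame(time = c(1, 1, 2, 3), event = c(1, 1, 1, 0))
  kmt <- kmEstimate(dt)
  sft <- summary(survival::survfit(survival::Surv(time, event) ~ 1,
                                   data = dt), times = kmt$time)
  expect_equal(kmt$survival, sft$surv, tolerance = 1e-12)
})

test_that("expression stratification yields ordered near-equal bins", {
  expect_equal(stratifyExpression(1:8, 4), rep(1:4, each = 2))
  x <- c(5, 1, 9, 3, 7, 2, 8, 4)
  g <- stratifyExpression(x, 4)
  expect_equal(g[order(x)], rep(1:4, each = 2))
  expect_true(all(diff(g[order(x)]) >= 0))
  expect_error(stratifyExpression(rep(1, 8), 4), "constant")
  expect_error(stratifyExpression(1:3, 4), "nGroups")
})

test_that("Cox fit matches survival::coxph and its invariances", {
  coh <- generateSurvivalCohort(200, geneHr = 1.8, seed = 17)
  cw <- coxWald(coh)
  ref <- survival::coxph(survival::Surv(time, event) ~ expr, data = coh,
                         ties = "breslow")
  expect_equal(cw$beta, unname(coef(ref)), tolerance = 1e-6)
  expect_equal(cw$se, sqrt(unname(vcov(ref)[1, 1])), tolerance = 1e-6)
  expect_lt(abs(cw$scoreResidual), 1e-8)

  # covariate rescaling: beta scales by 1/c, Wald z unchanged
  coh2 <- coh; coh2$expr <- coh$expr * 3
  cw2 <- coxWald(coh2)
  expect_equal(cw2$beta, cw$beta / 3, tolerance = 1e-7)
  expect_equal(cw2$waldZ, cw$waldZ, tolerance = 1e-7)

  # null: identical survival in identical covariate groups
  nullD <- data.frame(time = rep(c(1, 2, 3, 4, 5), 2),
                      event = rep(1, 10),
                      expr = rep(c(0, 1), each = 5))
  cwN <- coxWald(nullD)
  expect_lt(abs(cwN$beta), 1e-6)
  expect_gt(cwN$pval, 0.99)

  expect_error(coxWald(data.frame(time = 1:5, event = 0,
                                  expr = rnorm(5))), "events")
  expect_error(coxWald(data.frame(time = 1:5, event = 1, expr = 1)),
               "constant")
})

test_that("Fisher integration matches chi-square closed forms", {
  # k = 1 identity
  expect_equal(fisherIntegrate(0.37)$pval, 0.37, tolerance = 1e-12)
  # no evidence
  r11 <- fisherIntegrate(c(1, 1))
  expect_equal(r11$X2, 0)
  expect_equal(r11$pval, 1)
  # (0.5, 0.5)
  r <- fisherIntegrate(c(0.5, 0.5))
  expect_equal(r$X2, 2.7726, tolerance = 1e-4)
  expect_equal(r$df, 4L)
  expect_equal(r$pval, 0.5966, tolerance = 1e-4)
  expect_error(fisherIntegrate(c(0, 0.5)), "\\(0, 1\\]")
  expect_error(fisherIntegrate(numeric()), "at least one")

  # permutation invariance and monotonicity
  p <- c(0.1, 0.4, 0.8)
  expect_equal(fisherIntegrate(p)$pval, fisherIntegrate(rev(p))$pval)
  expect_lt(fisherIntegrate(c(0.05, 0.4, 0.8))$pval,
            fisherIntegrate(p)$pval)
})

test_that("evidence integration ranks TFs by combined p", {
  tbl <- matrix(c(0.01, 0.02,
                  0.5, 0.5), nrow = 2, byrow = TRUE,
                dimnames = list(c("tfA", "tfB"), c("s1", "s2")))
  out <- integrateEvidence(tbl)
  expect_equal(out$tf, c("tfA", "tfB"))
  # -2(log 0.01 + log 0.02) = 17.034 on 4 df
  expect_equal(out$pIntegrated[1], 0.0019034, tolerance = 1e-3)
  expect_lt(out$pIntegrated[1], 0.01)
  expect_equal(out$pIntegrated[2], 0.5966, tolerance = 1e-4)
  expect_equal(out$rank, 1:2)

  # all-ones row ranks last; missing entries adjust df
  tbl2 <- rbind(tbl, tfC = c(1, 1), tfD = c(0.3, NA))
  out2 <- integrateEvidence(tbl2)
  expect_equal(out2$tf[nrow(out2)], "tfC")
  expect_equal(out2$df[out2$tf == "tfD"], 2L)
  expect_equal(out2$pIntegrated[out2$tf == "tfD"], 0.3, tolerance = 1e-12)

  # a TF with no sources is excluded with a message
  tbl3 <- rbind(tbl, tfE = c(NA, NA))
  expect_message(out3 <- integrateEvidence(tbl3), "tfE")
  expect_false("tfE" %in% out3$tf)
})

test_that("NES and rank conversions give valid one-sided p-values", {
  expect_equal(nesToOneSidedP(0), 0.5)
  expect_lt(nesToOneSidedP(-3), nesToOneSidedP(0))
  expect_gt(nesToOneSidedP(3), 0.99)
  expect_equal(rankToP(1, 100), 0.01)
  expect_equal(rankToP(100, 100), 1)
  expect_error(rankToP(0, 10))
})
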