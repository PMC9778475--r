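# Survival association (Kaplan-Meier, univariate Cox with Wald test) and
# Fisher p-value integration of multi-source TF evidence.

#' Kaplan-Meier product-limit estimate
#'
#' Right-continuous, non-increasing survival step function per group, with
#' S(0) = 1 and steps only at event times.
#'
#' @param records `data.frame` with columns `time` (> 0) and `event`
#'   (0/1).
#' @param groups Optional group label per record (default one group).
#' @return `data.frame(group, time, nRisk, nEvent, survival)`, one row per
#'   distinct event time per group.
#' @export
kmEstimate <- function(records, groups = NULL) {
  if (any(records$time <= 0)) stop("non-positive survival time")
  if (!all(records$event %in% c(0, 1))) stop("event must be 0/1")
  if (is.null(groups)) groups <- rep("all", nrow(records))
  if (length(groups) != nrow(records)) stop("one group per record required")
  out <- lapply(unique(as.character(groups)), function(g) {
    d <- records[groups == g, , drop = FALSE]
    if (!nrow(d)) return(NULL)
    tev <- sort(unique(d$time[d$event == 1]))
    if (!length(tev))
      return(data.frame(group = character(0), time = numeric(0),
                        nRisk = integer(0), nEvent = integer(0),
                        survival = numeric(0)))
    nRisk <- vapply(tev, function(t) sum(d$time >= t), integer(1))
    nEvent <- vapply(tev, function(t) sum(d$time == t & d$event == 1),
                     integer(1))
    data.frame(group = g, time = tev, nRisk = nRisk, nEvent = nEvent,
               survival = cumprod(1 - nEvent / nRisk))
  })
  do.call(rbind, out)
}

#' Quantile stratification of expression
#'
#' Splits samples into `nGroups` near-equal-sized bins of increasing
#' expression (1 = lowest).
#'
#' @param expr Per-sample expression (non-constant).
#' @param nGroups Number of strata (>= 2, <= number of samples).
#' @return Integer labels 1..nGroups, monotone in expression.
#' @examples
#' stratifyExpression(1:8, 4)
#' @export
stratifyExpression <- function(expr, nGroups = 4) {
  n <- length(expr)
  if (nGroups < 2 || n < nGroups)
    stop("need nGroups >= 2 and at least nGroups samples")
  if (length(unique(expr)) == 1) stop("constant expression")
  as.integer(ceiling(rank(expr, ties.method = "first") * nGroups / n))
}

#' Univariate Cox proportional-hazards fit with Wald test
#'
#' Maximizes the Breslow partial likelihood by Newton-Raphson with
#' step-halving (at most 50 iterations, convergence tolerance 1e-9 on
#' beta). The Wald statistic is `beta / se` with a two-sided normal
#' p-value.
#'
#' @param records `data.frame` with columns `time` (> 0), `event` (0/1,
#'   >= 2 events) and `expr` (non-constant covariate).
#' @return List with `beta`, `se`, `waldZ`, `pval`, `iterations`,
#'   `scoreResidual` (score equation value at the optimum).
#' @export
coxWald <- function(records) {
  time <- records$time; event <- records$event; x <- records$expr
  if (any(time <= 0)) stop("non-positive survival time")
  if (sum(event) < 2) stop("fewer than 2 events")
  if (length(unique(x)) == 1) stop("constant covariate")

  # Breslow log partial likelihood and derivatives at beta
  llik <- function(b) {
    eta <- b * x
    ll <- 0; U <- 0; I <- 0
    for (t in sort(unique(time[event == 1]))) {
      atRisk <- time >= t
      dead <- time == t & event == 1
      w <- exp(eta[atRisk])
      s0 <- sum(w)
      s1 <- sum(w * x[atRisk])
      s2 <- sum(w * x[atRisk]^2)
      d <- sum(dead)
      ll <- ll + sum(eta[dead]) - d * log(s0)
      U <- U + sum(x[dead]) - d * s1 / s0
      I <- I + d * (s2 / s0 - (s1 / s0)^2)
    }
    list(ll = ll, U = U, I = I)
  }

  beta <- 0
  cur <- llik(beta)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (cur$I <= 0) stop("singular information; covariate degenerate")
    step <- cur$U / cur$I
    # step-halving keeps the partial likelihood non-decreasing
    repeat {
      cand <- llik(beta + step)
      if (cand$ll >= cur$ll - 1e-12 || abs(step) < 1e-12) break
      step <- step / 2
    }
    beta <- beta + step
    cur <- cand
    if (abs(step) < 1e-9 || iter >= 50L) break
  }
  se <- 1 / sqrt(cur$I)
  z <- beta / se
  list(beta = beta, se = se, waldZ = z,
       pval = min(1, 2 * stats::pnorm(-abs(z))),
       iterations = iter, scoreResidual = cur$U)
}

#' Fisher p-value integration
#'
#' Combines k independent p-values via `X2 = -2 * sum(log(p))` against a
#' chi-square with 2k degrees of freedom.
#'
#' @param pvals Numeric vector of p-values in (0, 1\], length >= 1.
#' @return List with `X2`, `df`, `pval`.
#' @examples
#' fisherIntegrate(c(0.5, 0.5))  # X2 = 2.7726, p = 0.5966
#' @export
fisherIntegrate <- function(pvals) {
  if (!length(pvals)) stop("need at least one p-value")
  if (any(pvals <= 0) || any(pvals > 1))
    stop("p-values must lie in (0, 1]; floor zeros upstream")
  X2 <- -2 * sum(log(pvals))
  df <- 2L * length(pvals)
  list(X2 = X2, df = df,
       pval = stats::pchisq(X2, df, lower.tail = FALSE))
}

#' Convert a signed NES to a one-sided p-value (repression direction)
#'
#' Small p means strong repression (very negative NES).
#'
#' @param nes Numeric NES values.
#' @param pFloor Floor keeping p positive (default 1e-300).
#' @return One-sided p-values in (0, 1\].
#' @export
nesToOneSidedP <- function(nes, pFloor = 1e-300) {
  pmin(1, pmax(stats::pnorm(nes), pFloor))
}

#' Convert ranks to p-values
#'
#' `p = rank / N`, for evidence sources reported as rankings.
#'
#' @param r Ranks (1 = strongest evidence).
#' @param N Number of ranked items.
#' @return p-values in (0, 1].
#' @export
rankToP <- function(r, N) {
  stopifnot(all(r >= 1), all(r <= N))
  r / N
}

#' Integrate multi-source TF evidence
#'
#' Per-TF Fisher integration across the available evidence sources
#' (missing entries are dropped and the degrees of freedom adjust);
#' TFs are ranked by integrated p ascending, ties broken by TF
#' identifier. TFs with no available source are excluded with a message.
#' Signed evidence (NES values) must be converted upstream to one-sided
#' p-values in the direction of interest, e.g. with [nesToOneSidedP()].
#'
#' @param tbl Numeric matrix or `data.frame` of p-values, TFs as rows
#'   (rownames), evidence sources as columns; NA = missing.
#' @return `data.frame(tf, nSources, X2, df, pIntegrated, rank)`, ordered
#'   by rank.
#' @export
integrateEvidence <- function(tbl) {
  m <- as.matrix(tbl)
  if (is.null(rownames(m))) stop("evidence table needs TF rownames")
  ok <- !is.na(m)
  if (any(m[ok] <= 0) || any(m[ok] > 1))
    stop("p-values must lie in (0, 1]")
  rows <- lapply(rownames(m), function(tf) {
    p <- m[tf, ok[tf, ]]
    if (!length(p)) {
      message("excluding TF ", tf, ": no evidence sources available")
      return(NULL)
    }
    fi <- fisherIntegrate(p)
    data.frame(tf = tf, nSources = length(p), X2 = fi$X2, df = fi$df,
               pIntegrated = fi$pval)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no TF has any evidence source")
  out <- out[order(out$pIntegrated, out$tf), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
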