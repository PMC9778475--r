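#' Gene identifiers for a synthetic universe
#'
#' @param n Number of genes.
#' @return Character vector `gene_00001 ... gene_n`.
#' @export
geneIds <- function(n) sprintf("gene_%05d", seq_len(n))

#' SimConfig: parameters of the synthetic hashed two-condition experiment
#'
#' Defaults emulate the study design the package targets: two hashed
#' conditions (vehicle control vs drug) pooled on one lane, ~2,500 cells,
#' ~18,000 detected genes, log-normal library-size variation,
#' negative-binomial counts, condition effects concentrated on the targets
#' of selected TF regulons, and three cell-cycle phase programs whose
#' per-group fractions default to a drug-induced G1 arrest
#' (control 25.39/49.52/25.09 vs treated 47.65/36.25/16.10 percent for
#' G1/S/G2M).
#'
#' @slot nCellsPerGroup Cells per condition (default 1250).
#' @slot nGenes Genes in the universe (default 18000).
#' @slot nHashtags Number of hashtags; fixed at 2 in this design.
#' @slot multipletRate Fraction of additional ambiguous-droplet cells
#'   relative to the total of singlets (default 0.072).
#' @slot librarySizeLogMean,librarySizeLogSd Log-normal parameters of
#'   per-cell library size (defaults log(20000) and 0.4).
#' @slot nbDispersion Shared negative-binomial dispersion (Var = mu +
#'   dispersion * mu^2; default 0.3).
#' @slot perturbedTfs `data.frame(tf, effect)`: log-scale shift applied to
#'   each TF's targets (times the mode of regulation) in the treated group.
#' @slot phaseFractions 2 x 3 matrix (rows `ctr`, `pnb`; columns `G1`,
#'   `S`, `G2M`) of cell-cycle phase fractions, each row summing to 1.
#' @slot phaseProgramSize Marker genes per phase program (default 50).
#' @slot phaseShift Multiplicative up-shift of program genes in cells of
#'   the matching phase (default 2).
#' @slot hashtagSignalMean,hashtagBackgroundMean Poisson means of a cell's
#'   own and cross hashtag counts (defaults 200 and 2).
#' @slot seed Master seed; fully determines the generated data.
#' @seealso [simConfig()], [generateDataset()]
#' @export
setClass("SimConfig", representation(
  nCellsPerGroup = "integer", nGenes = "integer", nHashtags = "integer",
  multipletRate = "numeric", librarySizeLogMean = "numeric",
  librarySizeLogSd = "numeric", nbDispersion = "numeric",
  perturbedTfs = "data.frame", phaseFractions = "matrix",
  phaseProgramSize = "integer", phaseShift = "numeric",
  hashtagSignalMean = "numeric", hashtagBackgroundMean = "numeric",
  seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nCellsPerGroup < 1L) msg <- c(msg, "nCellsPerGroup must be >= 1")
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
  if (object@nHashtags != 2L) msg <- c(msg, "this design uses exactly 2 hashtags")
  if (object@multipletRate < 0 || object@multipletRate > 1)
    msg <- c(msg, "multipletRate must lie in [0, 1]")
  if (object@nbDispersion <= 0) msg <- c(msg, "nbDispersion must be positive")
  if (object@librarySizeLogSd < 0) msg <- c(msg, "librarySizeLogSd must be >= 0")
  pf <- object@phaseFractions
  if (!all(dim(pf) == c(2L, 3L)) ||
      !identical(colnames(pf), c("G1", "S", "G2M")) ||
      !identical(rownames(pf), c("ctr", "pnb")))
    msg <- c(msg, "phaseFractions must be a 2x3 matrix (ctr/pnb x G1/S/G2M)")
  else if (any(abs(rowSums(pf) - 1) > 1e-8) || any(pf < 0))
    msg <- c(msg, "phase fractions must be non-negative and sum to 1 per group")
  pt <- object@perturbedTfs
  if (!all(c("tf", "effect") %in% names(pt)))
    msg <- c(msg, "perturbedTfs needs columns tf, effect")
  else if (nrow(pt) && !all(is.finite(pt$effect)))
    msg <- c(msg, "perturbation effects must be finite")
  if (object@hashtagSignalMean <= 0 || object@hashtagBackgroundMean <= 0)
    msg <- c(msg, "hashtag means must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a SimConfig
#'
#' @param nCellsPerGroup,nGenes,multipletRate,librarySizeLogMean,librarySizeLogSd,nbDispersion,phaseProgramSize,phaseShift,hashtagSignalMean,hashtagBackgroundMean,seed
#'   See [SimConfig-class] for meanings and defaults.
#' @param perturbedTfs `data.frame(tf, effect)` of planted regulon
#'   perturbations (default: none).
#' @param phaseFractions 2 x 3 matrix of per-group phase fractions; see
#'   [SimConfig-class].
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nCellsPerGroup = 100, nGenes = 500, seed = 1)
#' @export
simConfig <- function(nCellsPerGroup = 1250L, nGenes = 18000L,
                      multipletRate = 0.072,
                      librarySizeLogMean = log(20000),
                      librarySizeLogSd = 0.4,
                      nbDispersion = 0.3,
                      perturbedTfs = data.frame(tf = character(),
                                                effect = numeric()),
                      phaseFractions = defaultPhaseFractions(),
                      phaseProgramSize = 50L, phaseShift = 2,
                      hashtagSignalMean = 200,
                      hashtagBackgroundMean = 2, seed = 1L) {
  new("SimConfig",
      nCellsPerGroup = as.integer(nCellsPerGroup),
      nGenes = as.integer(nGenes), nHashtags = 2L,
      multipletRate = multipletRate,
      librarySizeLogMean = librarySizeLogMean,
      librarySizeLogSd = librarySizeLogSd,
      nbDispersion = nbDispersion,
      perturbedTfs = perturbedTfs,
      phaseFractions = phaseFractions,
      phaseProgramSize = as.integer(phaseProgramSize),
      phaseShift = phaseShift,
      hashtagSignalMean = hashtagSignalMean,
      hashtagBackgroundMean = hashtagBackgroundMean,
      seed = as.integer(seed))
}

#' Default per-group cell-cycle phase fractions
#'
#' Control cells cycle freely; treated cells show a G1 arrest.
#' @return 2 x 3 matrix, rows `ctr`/`pnb`, columns `G1`/`S`/`G2M`.
#' @export
defaultPhaseFractions <- function() {
  matrix(c(0.2539, 0.4952, 0.2509,
           0.4765, 0.3625, 0.1610),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("ctr", "pnb"), c("G1", "S", "G2M")))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nCellsPerGroup, "cells/group,",
      object@nGenes, "genes,", nrow(object@perturbedTfs),
      "perturbed TFs, multiplet rate", object@multipletRate,
      ", seed", object@seed, "\n")
})

#' Generate a synthetic TF regulon network
#'
#' Draws `nTfs` TF genes from the gene universe and, for each, a regulon of
#' `targetsPerTf` distinct target genes with random modes of regulation
#' (activating with probability 0.7) and likelihood weights uniform on
#' (0.2, 1]. Regulons may share targets, as real cohort-derived networks do.
#'
#' @param nTfs Number of TFs (>= 1).
#' @param targetsPerTf Targets per regulon (>= 2).
#' @param genes Gene universe to draw from; must exceed `targetsPerTf`.
#' @param seed Seed; the output is fully determined by it.
#' @return A [RegulonNetwork-class].
#' @examples
#' net <- generateNetwork(5, 10, genes = geneIds(200), seed = 1)
#' @export
generateNetwork <- function(nTfs, targetsPerTf, genes = geneIds(2000),
                            seed = 1) {
  if (nTfs < 1 || targetsPerTf < 2)
    stop("nTfs must be >= 1 and targetsPerTf >= 2")
  if (length(genes) <= targetsPerTf + nTfs)
    stop("gene universe too small for requested network")
  withSeed(seed, {
    tfs <- sample(genes, nTfs)
    regs <- lapply(tfs, function(tf) {
      tg <- sample(setdiff(genes, tf), targetsPerTf)
      regulon(tf, tg,
              mor = sample(c(1, -1), targetsPerTf, replace = TRUE,
                           prob = c(0.7, 0.3)),
              likelihood = stats::runif(targetsPerTf, 0.2, 1))
    })
    regulonNetwork(regs)
  })
}

#' Resample a network into a cohort-style replicate
#'
#' Emulates a second, independently inferred network over the same biology:
#' each regulon keeps a random subset of its targets (at least 2) and its
#' likelihoods are jittered, while modes of regulation are preserved.
#' Running master-regulator analysis on two such replicates supports the
#' two-network consensus.
#'
#' @param network A [RegulonNetwork-class].
#' @param keepFrac Fraction of targets retained per regulon (default 0.7).
#' @param likelihoodSd SD of Gaussian jitter on likelihoods (default 0.1);
#'   jittered values are clamped to (0.05, 1].
#' @param seed Seed.
#' @return A [RegulonNetwork-class] over the same TFs.
#' @export
perturbNetwork <- function(network, keepFrac = 0.7, likelihoodSd = 0.1,
                           seed = 1) {
  stopifnot(is(network, "RegulonNetwork"), keepFrac > 0, keepFrac <= 1)
  withSeed(seed, {
    regs <- lapply(as.list(network), function(r) {
      tg <- regulonTargets(r)
      k <- max(2L, round(keepFrac * nrow(tg)))
      tg <- tg[sample(nrow(tg), k), , drop = FALSE]
      lik <- tg$likelihood + stats::rnorm(k, 0, likelihoodSd)
      tg$likelihood <- pmin(pmax(lik, 0.05), 1)
      regulon(regulonTF(r), tg$target, tg$mor, tg$likelihood)
    })
    regulonNetwork(regs)
  })
}

#' Generate a hashed two-condition single-cell dataset with planted truth
#'
#' Counts follow a negative-binomial model: gene baseline abundances are
#' drawn log-normally and scaled by log-normal per-cell library-size
#' factors. In treated (`pnb`) cells, targets of each perturbed TF have
#' their means shifted on the log scale by `mor * effect` (and the TF's own
#' mean by `effect`). Disjoint S and G2M marker programs (G1 has none) are
#' multiplicatively elevated in cells of the matching phase. Each singlet's
#' own hashtag is Poisson around the signal mean and its cross hashtag
#' around the background mean; multiplets receive the signal mean on both.
#'
#' @param config A [SimConfig-class].
#' @param network A [RegulonNetwork-class] whose TFs and targets lie inside
#'   `geneIds(config@nGenes)`; required when `config` plants perturbations.
#' @return A [SingleCellExperiment::SingleCellExperiment] with assay
#'   `counts` (sparse), `colData` columns `hashtag1`, `hashtag2`,
#'   `trueGroup` (`ctr`/`pnb`/`multiplet`), `truePhase`, `trueMultiplet`,
#'   `trueLibrarySize`, and `metadata()` entries `config`, `perturbedTfs`,
#'   `phasePrograms` (list of S/G2M marker vectors).
#' @examples
#' cfg <- simConfig(nCellsPerGroup = 50, nGenes = 300, seed = 1)
#' sce <- generateDataset(cfg)
#' @export
generateDataset <- function(config, network = NULL) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  genes <- geneIds(config@nGenes)
  pt <- config@perturbedTfs
  if (nrow(pt)) {
    if (is.null(network))
      stop("a network is required when perturbedTfs is non-empty")
    missing <- setdiff(pt$tf, names(network))
    if (length(missing))
      stop("perturbed TFs not in network: ", paste(missing, collapse = ", "))
  }
  if (!is.null(network)) {
    netGenes <- unique(c(names(network),
                         unlist(lapply(as.list(network),
                                       function(r) regulonTargets(r)$target))))
    if (!all(netGenes %in% genes))
      stop("network genes outside the configured gene universe")
  } else netGenes <- character()

  withSeed(config@seed, {
    nPerGroup <- config@nCellsPerGroup
    nSing <- 2L * nPerGroup
    nMult <- as.integer(round(config@multipletRate * nSing))
    nCells <- nSing + nMult
    group <- c(rep("ctr", nPerGroup), rep("pnb", nPerGroup),
               rep("multiplet", nMult))
    isMult <- group == "multiplet"

    # gene baseline relative abundance (log-normal), normalized
    base <- stats::rlnorm(config@nGenes, meanlog = 0, sdlog = 1.2)
    prop <- base / sum(base)

    # phase programs: disjoint markers, preferentially outside the network
    pool <- setdiff(genes, netGenes)
    if (length(pool) < 2L * config@phaseProgramSize)
      pool <- genes
    prog <- sample(pool, 2L * config@phaseProgramSize)
    sProgram <- prog[seq_len(config@phaseProgramSize)]
    g2mProgram <- prog[config@phaseProgramSize + seq_len(config@phaseProgramSize)]
    sIdx <- match(sProgram, genes)
    g2mIdx <- match(g2mProgram, genes)

    # per-cell phases: multiplets cycle like controls
    phaseOf <- function(grp) {
      fr <- config@phaseFractions[if (grp == "pnb") "pnb" else "ctr", ]
      sample(colnames(config@phaseFractions), 1, prob = fr)
    }
    phase <- vapply(group, phaseOf, character(1), USE.NAMES = FALSE)

    # treated-group log-scale perturbation multipliers
    pnbMult <- rep(1, config@nGenes)
    if (nrow(pt)) {
      for (i in seq_len(nrow(pt))) {
        r <- network[[pt$tf[i]]]
        tg <- regulonTargets(r)
        j <- match(tg$target, genes)
        pnbMult[j] <- pnbMult[j] * exp(tg$mor * pt$effect[i])
        pnbMult[match(pt$tf[i], genes)] <-
          pnbMult[match(pt$tf[i], genes)] * exp(pt$effect[i])
      }
    }

    libSize <- stats::rlnorm(nCells, config@librarySizeLogMean,
                             config@librarySizeLogSd)

    size <- 1 / config@nbDispersion
    cols <- vector("list", nCells)
    for (c in seq_len(nCells)) {
      mu <- prop * libSize[c]
      if (group[c] == "pnb") mu <- mu * pnbMult
      if (phase[c] == "S") mu[sIdx] <- mu[sIdx] * config@phaseShift
      if (phase[c] == "G2M") mu[g2mIdx] <- mu[g2mIdx] * config@phaseShift
      cols[[c]] <- stats::rnbinom(config@nGenes, mu = mu, size = size)
    }
    counts <- Matrix::Matrix(
      matrix(unlist(cols), nrow = config@nGenes, ncol = nCells),
      sparse = TRUE)
    rownames(counts) <- genes
    colnames(counts) <- sprintf("cell_%05d", seq_len(nCells))

    h1 <- integer(nCells); h2 <- integer(nCells)
    sig <- config@hashtagSignalMean; bg <- config@hashtagBackgroundMean
    h1[group == "ctr"] <- stats::rpois(sum(group == "ctr"), sig)
    h2[group == "ctr"] <- stats::rpois(sum(group == "ctr"), bg)
    h1[group == "pnb"] <- stats::rpois(sum(group == "pnb"), bg)
    h2[group == "pnb"] <- stats::rpois(sum(group == "pnb"), sig)
    h1[isMult] <- stats::rpois(nMult, sig)
    h2[isMult] <- stats::rpois(nMult, sig)

    cd <- S4Vectors::DataFrame(
      hashtag1 = h1, hashtag2 = h2,
      trueGroup = group, truePhase = phase, trueMultiplet = isMult,
      trueLibrarySize = Matrix::colSums(counts),
      row.names = colnames(counts))
    SingleCellExperiment::SingleCellExperiment(
      assays = list(counts = counts), colData = cd,
      metadata = list(config = config, perturbedTfs = pt,
                      phasePrograms = list(S = sProgram, G2M = g2mProgram)))
  })
}

#' Generate a synthetic survival cohort for one gene
#'
#' Event times are exponential with hazard `h0 * exp(beta * expr)`,
#' `beta = log(geneHr)`, expression standard normal across samples, and an
#' independent exponential censoring time calibrated so that roughly
#' `censorRate` of the cohort is censored under the null.
#'
#' @param n Cohort size (>= 10).
#' @param geneHr True hazard ratio per unit of expression (> 0).
#' @param censorRate Expected censored fraction, in \[0, 1).
#' @param seed Seed.
#' @param baselineHazard Baseline exponential hazard (default 0.1).
#' @return `data.frame(sample, time, event, expr)` with `time > 0` and
#'   `event` in 0/1.
#' @examples
#' coh <- generateSurvivalCohort(100, geneHr = 2, seed = 11)
#' @export
generateSurvivalCohort <- function(n, geneHr, censorRate = 0.3, seed = 1,
                                   baselineHazard = 0.1) {
  if (n < 10) stop("n must be >= 10")
  if (geneHr <= 0) stop("geneHr must be positive")
  if (censorRate < 0 || censorRate >= 1)
    stop("censorRate must lie in [0, 1)")
  withSeed(seed, {
    expr <- stats::rnorm(n)
    beta <- log(geneHr)
    evTime <- stats::rexp(n, rate = baselineHazard * exp(beta * expr))
    if (censorRate > 0) {
      cRate <- baselineHazard * censorRate / (1 - censorRate)
      cTime <- stats::rexp(n, rate = cRate)
    } else cTime <- rep(Inf, n)
    data.frame(sample = sprintf("s%04d", seq_len(n)),
               time = pmin(evTime, cTime),
               event = as.integer(evTime <= cTime),
               expr = expr)
  })
}
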