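# End-to-end orchestration: demux -> QC -> normalize -> cell cycle -> DE ->
# GSEA -> MRA (two networks + consensus) -> pseudobulk/Spearman ->
# survival/evidence. Every stage writes a plain-text artifact and the run
# ends with a machine-readable JSON summary.

#' Spearman correlation coefficient
#'
#' Pearson correlation of mid-ranks (average-rank ties).
#'
#' @param x,y Numeric vectors over the same genes (length >= 3,
#'   non-constant).
#' @return Correlation in \[-1, 1\].
#' @examples
#' spearmanCC(c(1, 2, 3), c(2, 1, 3))  # 0.5
#' @export
spearmanCC <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 shared genes")
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    stop("constant vector")
  stats::cor(x, y, method = "spearman")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path File ending in `.yaml`/`.yml` or `.json`.
#' @return A named list for [runPipeline()].
#' @export
readPipelineConfig <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                        simplifyVector = TRUE)
  else stop("config must be YAML or JSON")
}

.logStage <- function(log, stage, detail) {
  line <- sprintf("[%s] %s", stage, detail)
  cat(line, "\n", sep = "", file = log, append = TRUE)
  invisible(line)
}

#' Run the full analysis pipeline
#'
#' Executes every stage on either a synthetic experiment (config entry
#' `sim`, a [SimConfig-class] or argument list for [simConfig()]) or real
#' inputs (config entry `input`: paths `counts` (MTX dir), `hashtags`
#' (CSV), `networkA`/`networkB` (regulon TSVs), optional `markers` (GMT
#' with sets `S` and `G2M`), optional `geneSets` (GMT), optional
#' `survival` (named list of CSVs per TF)). Exactly one of `sim`/`input`
#' must be present. In synthetic mode the companion truth network is
#' generated alongside and the second network is a cohort-style resample
#' of it; survival cohorts are simulated with hazard ratio
#' `survivalHr` for TFs planted with negative effects and 1 otherwise.
#'
#' Stage parameters (all optional, with defaults):
#' `ratioThreshold` (10), `minGenes` (1000), `minCells` (3),
#' `scaleFactor` (1e4), `padjMax` (0.01), `lfcMin` (1), `nPerm` (1000),
#' `weight` (1), `nBins` (24), `nCtrl` (100), `topK` (10, TFs taken into
#' evidence integration), `survivalN` (300), `survivalHr` (2),
#' `censorRate` (0.3), `nTfs` (50), `targetsPerTf` (40, synthetic network
#' size), `perCellCells` (0; > 0 computes per-cell pathway NES and TF
#' activity on that many cells), `seed` (1).
#'
#' @param config Named list (or path to YAML/JSON) as above.
#' @param outDir Output directory; all stage artifacts, `summary.json`
#'   and `run.log` are written here.
#' @return Invisibly, the summary list (also serialized to
#'   `summary.json`).
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config)) config <- readPipelineConfig(config)
  if (is.null(config$sim) && is.null(config$input))
    stop("configuration error: provide either 'sim' or 'input'")
  if (!is.null(config$sim) && !is.null(config$input))
    stop("configuration error: provide only one of 'sim' and 'input'")
  prm <- function(name, default)
    if (!is.null(config[[name]])) config[[name]] else default
  seed <- prm("seed", 1L)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  log <- file.path(outDir, "run.log")
  cat("", file = log)
  .logStage(log, "start", paste0("scmra ",
    as.character(utils::packageVersion("scmra")),
    ", R ", getRversion(), ", seed ", seed))
  summary <- list(seed = seed)

  # ---- inputs -------------------------------------------------------
  if (!is.null(config$sim)) {
    sim <- config$sim
    if (!is(sim, "SimConfig")) sim <- do.call(simConfig, sim)
    netA <- if (!is.null(config$network)) config$network
      else generateNetwork(prm("nTfs", 50L), prm("targetsPerTf", 40L),
                           genes = geneIds(sim@nGenes),
                           seed = childSeed(seed, 1L))
    if (nrow(sim@perturbedTfs) && !all(sim@perturbedTfs$tf %in% names(netA)))
      sim@perturbedTfs$tf <- names(netA)[seq_len(nrow(sim@perturbedTfs))]
    sce <- generateDataset(sim, netA)
    summary$plantedTfs <- sim@perturbedTfs
    netB <- perturbNetwork(netA, seed = childSeed(seed, 2L))
    markers <- S4Vectors::metadata(sce)$phasePrograms
    counts <- SummarizedExperiment::assay(sce, "counts")
    hashtags <- data.frame(barcode = colnames(sce),
                           hashtag1 = sce$hashtag1,
                           hashtag2 = sce$hashtag2)
    truth <- as.data.frame(SummarizedExperiment::colData(sce))
    utils::write.csv(truth, file.path(outDir, "truth.csv"),
                     row.names = FALSE)
    writeRegulons(netA, file.path(outDir, "network_a.tsv"))
    writeRegulons(netB, file.path(outDir, "network_b.tsv"))
  } else {
    inp <- config$input
    counts <- readCountsMTX(inp$counts)
    hashtags <- readHashtags(inp$hashtags)
    netA <- readRegulons(inp$networkA)
    netB <- if (!is.null(inp$networkB)) readRegulons(inp$networkB) else netA
    markers <- if (!is.null(inp$markers)) readGMT(inp$markers) else NULL
    truth <- NULL
    sce <- NULL
  }
  .logStage(log, "input", sprintf("counts %d genes x %d cells, %d + %d regulons",
    nrow(counts), ncol(counts), length(netA), length(netB)))

  # ---- demultiplexing ----------------------------------------------
  dm <- demultiplex(hashtags, prm("ratioThreshold", 10))
  utils::write.csv(data.frame(barcode = names(dm$labels),
                              label = unname(dm$labels)),
                   file.path(outDir, "labels.csv"), row.names = FALSE)
  summary$demux <- as.list(dm$summary)
  if (!is.null(truth)) {
    sing <- !truth$trueMultiplet
    summary$demuxAccuracy <-
      100 * mean(dm$labels[sing] == truth$trueGroup[sing])
  }
  .logStage(log, "demux", paste(names(dm$summary), dm$summary,
                                collapse = ", "))

  # ---- QC and normalization ----------------------------------------
  keep <- dm$labels[colnames(counts)] != "multiplet"
  m <- counts[, keep, drop = FALSE]
  labels <- dm$labels[colnames(m)]
  m <- filterCells(m, prm("minGenes", 1000))
  m <- filterGenes(m, prm("minCells", 3))
  labels <- labels[colnames(m)]
  if (!ncol(m)) stop("stage qc: no cells survive filtering")
  nm <- logNormalize(m, prm("scaleFactor", 1e4))
  gs <- geneStats(nm)
  utils::write.csv(gs, file.path(outDir, "gene_stats.csv"),
                   row.names = FALSE)
  summary$qc <- list(nGenes = nrow(m), nCells = ncol(m),
                     nCtr = sum(labels == "ctr"),
                     nPnb = sum(labels == "pnb"))
  .logStage(log, "qc", sprintf("%d genes x %d cells after filtering",
                               nrow(m), ncol(m)))

  # ---- cell cycle ---------------------------------------------------
  if (!is.null(markers) && all(c("S", "G2M") %in% names(markers))) {
    ps <- phaseScores(nm, markers$S, markers$G2M,
                      nBins = prm("nBins", 24), nCtrl = prm("nCtrl", 100),
                      seed = childSeed(seed, 3L))
    utils::write.csv(ps, file.path(outDir, "phase_scores.csv"),
                     row.names = FALSE)
    pf <- phaseFractions(ps$phase, labels)
    utils::write.csv(pf, file.path(outDir, "phase_fractions.csv"),
                     row.names = FALSE)
    summary$phaseFractions <- pf
    if (!is.null(truth)) {
      tp <- truth[ps$barcode, "truePhase"]
      summary$phaseAccuracy <- 100 * mean(ps$phase == tp)
    }
    .logStage(log, "cellcycle", sprintf("%d cells scored", nrow(ps)))
  }

  # ---- differential expression -------------------------------------
  sig <- deSignature(nm, labels, treated = "pnb", control = "ctr")
  utils::write.csv(sig, file.path(outDir, "signature.csv"),
                   row.names = FALSE)
  des <- deSummary(sig, prm("padjMax", 0.01), prm("lfcMin", 1))
  summary$de <- des
  .logStage(log, "diffexp", sprintf("%d up, %d down of %d genes",
                                    des$nUp, des$nDown, nrow(sig)))

  # ---- pseudobulk and bulk-style comparison ------------------------
  pb <- pseudobulk(m, labels)
  utils::write.csv(data.frame(gene = rownames(pb), pb),
                   file.path(outDir, "pseudobulk.csv"), row.names = FALSE)
  ctrCells <- which(labels == "ctr")
  half <- withSeed(childSeed(seed, 4L),
                   sample(ctrCells, floor(length(ctrCells) / 2)))
  pbA <- Matrix::rowSums(m[, half, drop = FALSE])
  pbB <- Matrix::rowSums(m[, setdiff(ctrCells, half), drop = FALSE])
  expressed <- pbA + pbB > 0
  summary$sccControlSplit <-
    spearmanCC(rpm(pbA[expressed] + 1e-9), rpm(pbB[expressed] + 1e-9))
  summary$sccTreatedVsControl <-
    spearmanCC(rpm(pb[, "ctr"] + 1e-9), rpm(pb[, "pnb"] + 1e-9))
  .logStage(log, "pseudobulk", sprintf(
    "SCC ctr split-half %.3f, pnb vs ctr %.3f",
    summary$sccControlSplit, summary$sccTreatedVsControl))

  # ---- gene-set enrichment -----------------------------------------
  sets <- if (!is.null(config$input) && !is.null(config$input$geneSets))
    readGMT(config$input$geneSets)
  else if (!is.null(markers))
    c(markers["S"], markers["G2M"])
  else NULL
  if (!is.null(sce) && nrow(S4Vectors::metadata(sce)$perturbedTfs)) {
    for (tf in S4Vectors::metadata(sce)$perturbedTfs$tf) {
      tg <- regulonTargets(netA[[tf]])
      sets[[paste0("targets_up_", tf)]] <- tg$target[tg$mor > 0]
    }
  }
  if (!is.null(sets)) {
    scoreVec <- sig$signedScore
    names(scoreVec) <- sig$gene
    enr <- do.call(rbind, lapply(names(sets), function(nm2) {
      r <- tryCatch(gseaNES(scoreVec, sets[[nm2]],
                            weight = prm("weight", 1),
                            nPerm = prm("nPerm", 1000),
                            seed = childSeed(seed, 5L)),
                    error = function(e) NULL)
      if (is.null(r)) return(NULL)
      data.frame(set = nm2, es = r$es, nes = r$nes, pval = r$pval,
                 leadingEdgeSize = length(r$leadingEdge))
    }))
    utils::write.csv(enr, file.path(outDir, "enrichment.csv"),
                     row.names = FALSE)
    summary$enrichment <- enr
    .logStage(log, "gsea", sprintf("%d sets scored", nrow(enr)))
  }

  # ---- master regulator analysis -----------------------------------
  mraA <- mra(sig, netA, networkName = "networkA")
  mraB <- mra(sig, netB, networkName = "networkB")
  utils::write.csv(mraTable(mraA), file.path(outDir, "mra_a.csv"),
                   row.names = FALSE)
  utils::write.csv(mraTable(mraB), file.path(outDir, "mra_b.csv"),
                   row.names = FALSE)
  cons <- mraConsensus(mraA, mraB)
  utils::write.csv(cons, file.path(outDir, "mra_consensus.csv"),
                   row.names = FALSE)
  summary$topRepressedTfs <-
    utils::head(cons$tf[order(cons$nesCombined)], 5)
  .logStage(log, "mra", sprintf("%d TFs in consensus; most repressed: %s",
    nrow(cons), paste(summary$topRepressedTfs, collapse = ", ")))

  # ---- per-cell projections (optional) ------------------------------
  nPC <- prm("perCellCells", 0L)
  if (nPC > 0 && !is.null(sets)) {
    pcs <- perCellSignatures(nm)
    sub <- withSeed(childSeed(seed, 6L),
                    sample(ncol(pcs), min(nPC, ncol(pcs))))
    pce <- perCellEnrichment(pcs[, sub, drop = FALSE], sets,
                             weight = prm("weight", 1),
                             nPerm = max(100, prm("nPerm", 1000) %/% 5),
                             seed = childSeed(seed, 7L))
    utils::write.csv(data.frame(barcode = rownames(pce), pce),
                     file.path(outDir, "percell_nes.csv"),
                     row.names = FALSE)
    pct <- perCellTFActivity(pcs[, sub, drop = FALSE], netA)
    utils::write.csv(data.frame(barcode = rownames(pct), pct),
                     file.path(outDir, "percell_tf_activity.csv"),
                     row.names = FALSE)
    .logStage(log, "percell", sprintf("%d cells projected", length(sub)))
  }

  # ---- survival and evidence integration ---------------------------
  if (!is.null(config$sim)) {
    topK <- utils::head(cons$tf, prm("topK", 10))
    planted <- S4Vectors::metadata(sce)$perturbedTfs
    scoreVec <- sig$signedScore; names(scoreVec) <- sig$gene
    zAll <- signatureToZ(scoreVec)
    srcNames <- c("exp", "act_a", "act_b",
                  "surv_nbl1", "surv_nbl2", "surv_nbl3", "surv_pan")
    ev <- matrix(NA_real_, length(topK), length(srcNames),
                 dimnames = list(topK, srcNames))
    kmOut <- NULL
    for (i in seq_along(topK)) {
      tf <- topK[i]
      ev[tf, "exp"] <- if (tf %in% names(zAll))
        nesToOneSidedP(zAll[tf]) else NA_real_
      ta <- mraTable(mraA); tb <- mraTable(mraB)
      ev[tf, "act_a"] <- nesToOneSidedP(ta$nes[match(tf, ta$tf)])
      ev[tf, "act_b"] <- nesToOneSidedP(tb$nes[match(tf, tb$tf)])
      hr <- if (tf %in% planted$tf[planted$effect < 0])
        prm("survivalHr", 2) else 1
      for (j in 1:4) {
        coh <- generateSurvivalCohort(prm("survivalN", 300L), hr,
                                      prm("censorRate", 0.3),
                                      seed = childSeed(seed, 100L + 10L * i + j))
        cw <- coxWald(coh)
        # poor prognosis when high expression raises hazard: upper tail
        ev[tf, 3L + j] <- max(stats::pnorm(cw$waldZ, lower.tail = FALSE),
                              1e-300)
        if (i == 1L && j == 1L) {
          strata <- stratifyExpression(coh$expr, 4)
          kmOut <- kmEstimate(coh, paste0("q", strata))
          kmOut$tf <- tf
        }
      }
    }
    evRank <- integrateEvidence(ev)
    utils::write.csv(data.frame(tf = rownames(ev), ev),
                     file.path(outDir, "evidence.csv"), row.names = FALSE)
    utils::write.csv(evRank, file.path(outDir, "evidence_ranked.csv"),
                     row.names = FALSE)
    if (!is.null(kmOut))
      utils::write.csv(kmOut, file.path(outDir, "km_top_tf.csv"),
                       row.names = FALSE)
    summary$evidenceTop <- utils::head(evRank$tf, 5)
    .logStage(log, "evidence", sprintf("%d TFs integrated; top: %s",
      nrow(evRank), paste(summary$evidenceTop, collapse = ", ")))
  }

  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .logStage(log, "done", "summary.json written")
  invisible(summary)
}
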