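# stage log: parameter echo + warnings captured as JSON next to the outputs
.writeStageLog <- function(dir, stage, params, warnings = character()) {
  log <- list(stage = stage, params = params,
              warnings = as.character(warnings))
  jsonlite::write_json(log, file.path(dir, paste0(stage, "_log.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(log)
}

.collectWarnings <- function(expr) {
  warns <- character()
  value <- withCallingHandlers(expr, warning = function(w) {
    warns <<- c(warns, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  list(value = value, warnings = warns)
}

#' Pipeline stage: simulate a cohort and write it to disk
#'
#' @param outDir output directory (matrix TSVs, phenotype.tsv, truth.json).
#' @param config a [simulationConfig()]; built from `...` when NULL.
#' @param mode "direct-z" (default) or "timeseries" (writes per-subject
#'   T x N series instead of matrices, plus the phenotype).
#' @param ... passed to [simulationConfig()].
#' @return the simulated cohort object, invisibly.
#' @export
runSimulateStage <- function(outDir, config = NULL,
                             mode = c("direct-z", "timeseries"), ...) {
  mode <- match.arg(mode)
  if (is.null(config)) config <- simulationConfig(...)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (mode == "direct-z") {
    cohort <- simulateBehavior(simulateConnectomes(config), config)
    writeCohort(cohort, outDir)
  } else {
    cohort <- simulateTimeseries(config)
    ph <- cohort@phenotype
    for (k in seq_along(cohort@series)) {
      utils::write.table(
        cohort@series[[k]],
        file.path(outDir, paste0(names(cohort@series)[k], "_ts.tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE,
        col.names = length(cohort@regionLabels) > 0)
    }
    ph$NCT <- NA_real_; ph$DST <- NA_real_
    utils::write.table(ph, file.path(outDir, "phenotype.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  .writeStageLog(outDir, "simulate",
                 list(mode = mode, seed = config@seed,
                      nRegions = config@nRegions,
                      groupSizes = as.list(config@groupSizes)))
  invisible(cohort)
}

#' Pipeline stage: ROI time series to Fisher-z connectivity matrices
#'
#' Reads per-subject time-series TSVs (`<subject>_<session>_ts.tsv`) and a
#' phenotype table from `inDir`, discards initial volumes, applies the
#' temporal preprocessing chain, computes Fisher-z matrices and writes them
#' (plus the phenotype) to `outDir`.
#'
#' @param inDir,outDir directories.
#' @param lowHz,highHz band-pass edges.
#' @param samplingInterval seconds per volume.
#' @param discardVolumes initial volumes dropped before any processing.
#' @param order preprocessing order (see [preprocessTimeSeries()]).
#' @return the resulting [ConnectomeCohort-class], invisibly.
#' @export
runFcStage <- function(inDir, outDir, lowHz = 0.01, highHz = 0.08,
                       samplingInterval = 2.5, discardVolumes = 0L,
                       order = "bandpass_first") {
  ph <- readPhenotype(file.path(inDir, "phenotype.tsv"))
  mats <- lapply(seq_len(nrow(ph)), function(k) {
    f <- file.path(inDir,
                   paste0(ph$subject[k], "_", ph$session[k], "_ts.tsv"))
    if (!file.exists(f)) stop("missing time-series file: ", f)
    ts <- readRoiTimeSeries(f, samplingInterval)
    if (discardVolumes > 0L) {
      ts <- roiTimeSeries(ts[-seq_len(discardVolumes), , drop = FALSE],
                          samplingInterval, colnames(ts))
    }
    connectivityMatrix(preprocessTimeSeries(ts, lowHz = lowHz,
                                            highHz = highHz, order = order))
  })
  cohort <- ConnectomeCohort(mats, ph)
  writeCohort(cohort, outDir)
  .writeStageLog(outDir, "fc",
                 list(lowHz = lowHz, highHz = highHz,
                      samplingInterval = samplingInterval,
                      discardVolumes = discardVolumes, order = order))
  invisible(cohort)
}

#' Pipeline stage: NBS contrast between two cohort subsets
#'
#' @param matDir cohort directory (see [writeCohort()]).
#' @param groupA,groupB group labels of the two sides.
#' @param sessionA,sessionB session labels ("pre"/"post").
#' @param tail,primaryP,nPerm,seed,paired,paperLiteral see [nbsTest()].
#' @param outDir results directory: `nbs_result.json` (components as
#'   label pairs, sizes, corrected p, null histogram) plus one edge-list
#'   TSV per component significant at `alpha`.
#' @param alpha corrected level for writing component edge lists.
#' @return the [NbsResult-class], invisibly.
#' @export
runNbsStage <- function(matDir, outDir, groupA, groupB,
                        sessionA = "pre", sessionB = "pre",
                        tail = "greater", primaryP = 1e-4,
                        nPerm = 10000L, seed = 1L, paired = FALSE,
                        paperLiteral = FALSE, alpha = 0.05) {
  cohort <- readCohort(matDir)
  A <- subsetCohort(cohort, group = groupA, session = sessionA)
  B <- subsetCohort(cohort, group = groupB, session = sessionB)
  cw <- .collectWarnings(
    nbsTest(A, B, tail = tail, primaryP = primaryP, nPerm = nPerm,
            seed = seed, paired = paired, paperLiteral = paperLiteral))
  res <- cw$value
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  lab <- regionLabels(cohort)
  comps <- lapply(seq_along(res@components), function(k) {
    co <- res@components[[k]]
    p <- edgePairs(co$edges)
    list(edges = lapply(seq_len(nrow(p)), function(e) {
           if (length(lab)) c(lab[p[e, 1]], lab[p[e, 2]])
           else c(p[e, 1] - 1L, p[e, 2] - 1L)
         }),
         size = co$size, nNodes = length(co$nodes),
         correctedP = res@correctedP[k])
  })
  jsonlite::write_json(
    list(contrast = list(groupA = groupA, sessionA = sessionA,
                         groupB = groupB, sessionB = sessionB,
                         tail = tail),
         primaryP = primaryP, nPerm = nPerm, seed = seed,
         components = comps,
         nullMaxSizeHistogram = as.list(table(res@nullMaxSizes))),
    file.path(outDir, "nbs_result.json"), auto_unbox = TRUE, digits = NA)
  sig <- which(res@correctedP < alpha)
  for (k in sig) {
    es <- res@components[[k]]$edges
    if (length(lab)) es@regionLabels <- lab
    writeEdgeList(es, file.path(outDir, sprintf("nbs_component%d.tsv", k)))
  }
  .writeStageLog(outDir, "nbs",
                 list(groupA = groupA, groupB = groupB, tail = tail,
                      primaryP = primaryP, nPerm = nPerm, seed = seed),
                 cw$warnings)
  invisible(res)
}

#' Pipeline stage: cross-validated CPM on one cohort subset
#'
#' @param matDir cohort directory.
#' @param outDir results directory: `cpm_<score>.json` with per-fold
#'   selections, out-of-fold predictions, r, p and the consensus edge sets
#'   (0-based pairs), plus consensus edge-list TSVs.
#' @param score phenotype column ("DST" or "NCT").
#' @param tail predicting tail; default "positive" for DST, "negative"
#'   for NCT.
#' @param group,session cohort subset (default healthy controls).
#' @param k,thresholdP,seed see [cpmCrossval()].
#' @return the [CpmResult-class], invisibly.
#' @export
runCpmStage <- function(matDir, outDir, score = "DST", tail = NULL,
                        group = "HC", session = "pre", k = 5L,
                        thresholdP = 0.01, seed = 1L) {
  cohort <- readCohort(matDir)
  sub <- subsetCohort(cohort, group = group, session = session)
  if (is.null(tail)) tail <- if (score == "NCT") "negative" else "positive"
  cw <- .collectWarnings(
    cpmCrossval(sub, score, k = k, thresholdP = thresholdP, tail = tail,
                seed = seed))
  res <- cw$value
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  out <- list(
    score = score, tail = tail, k = k, thresholdP = thresholdP,
    seed = seed, nRegions = nRegions(cohort),
    rPredObs = res@rPredObs, pPredObs = res@pPredObs,
    predictions = res@predictions, observed = res@observed,
    folds = lapply(res@folds, function(f) {
      list(train = f$train, test = f$test,
           nPositive = length(f$selection@positive),
           nNegative = length(f$selection@negative),
           slope = f$slope, intercept = f$intercept)
    }),
    consensusPositive = .edgeSetToJson(res@consensusPositive),
    consensusNegative = .edgeSetToJson(res@consensusNegative),
    regionLabels = as.list(regionLabels(cohort))
  )
  jsonlite::write_json(out,
                       file.path(outDir, paste0("cpm_", score, ".json")),
                       auto_unbox = TRUE, digits = NA)
  for (whichTail in c("positive", "negative")) {
    es <- slot(res, paste0("consensus",
                           if (whichTail == "positive") "Positive"
                           else "Negative"))
    if (length(regionLabels(cohort))) {
      es@regionLabels <- regionLabels(cohort)
    }
    writeEdgeList(es, file.path(outDir, sprintf("cpm_%s_consensus_%s.tsv",
                                                score, whichTail)))
  }
  .writeStageLog(outDir, paste0("cpm_", score),
                 list(score = score, tail = tail, k = k,
                      thresholdP = thresholdP, seed = seed),
                 cw$warnings)
  invisible(res)
}

#' Pipeline stage: combine CPM consensus networks into one predictor
#'
#' Reads two CPM stage JSONs (typically the DST-positive and NCT-negative
#' models), takes the union of the requested consensus tails with per-edge
#' provenance, and writes the combined network.
#'
#' @param cpmJsonA,cpmJsonB paths to `cpm_*.json` files.
#' @param outDir results directory: `pmn.json` and `pmn_edges.tsv` (with
#'   provenance and node degrees).
#' @param tailA,tailB which consensus tail to take from each file.
#' @return the combined [EdgeSet-class], invisibly.
#' @export
runPmnStage <- function(cpmJsonA, cpmJsonB, outDir,
                        tailA = "positive", tailB = "negative") {
  readTail <- function(path, tail) {
    js <- jsonlite::read_json(path)
    field <- paste0("consensus", if (tail == "positive") "Positive"
                                 else "Negative")
    .edgeSetFromJson(js[[field]], js$nRegions,
                     unlist(js$regionLabels) %||% character())
  }
  a <- readTail(cpmJsonA, tailA)
  b <- readTail(cpmJsonB, tailB)
  pmn <- combineNetworks(a, b, tags = c(tailA, tailB))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(edges = .edgeSetToJson(pmn),
         provenance = edgeProvenance(pmn),
         nRegions = nRegions(pmn),
         regionLabels = as.list(regionLabels(pmn)),
         nodeDegrees = as.list(networkDegrees(pmn))),
    file.path(outDir, "pmn.json"), auto_unbox = TRUE, digits = NA)
  writeEdgeList(pmn, file.path(outDir, "pmn_edges.tsv"))
  .writeStageLog(outDir, "pmn", list(tailA = tailA, tailB = tailB))
  invisible(pmn)
}

#' Pipeline stage: moderated regression of brain-behavior coupling
#'
#' Computes each subject's strength on a fixed network (e.g. the combined
#' psychomotor network) and fits score ~ strength * group with
#' bias-corrected bootstrap CIs.
#'
#' @param matDir cohort directory.
#' @param pmnJson path to a `pmn.json` (or CPM consensus) edge-set file.
#' @param outDir results directory (`moderation_<score>.json`).
#' @param score phenotype column.
#' @param moderatorGroup group coded 1 in the moderator.
#' @param groups,session cohort subset analyzed (default both patient
#'   groups' post scans).
#' @param nBoot,ciLevel,seed see [moderatedRegression()].
#' @return the [ModerationResult-class], invisibly.
#' @export
runModerateStage <- function(matDir, pmnJson, outDir, score = "DST",
                             moderatorGroup = "OHE",
                             groups = c("nonOHE", "OHE"),
                             session = "post", nBoot = 10000L,
                             ciLevel = 0.95, seed = 1L) {
  cohort <- readCohort(matDir)
  sub <- subsetCohort(cohort, group = groups, session = session)
  js <- jsonlite::read_json(pmnJson)
  edges <- .edgeSetFromJson(js$edges, js$nRegions,
                            unlist(js$regionLabels) %||% character())
  strengths <- networkStrength(sub, edges)
  ph <- phenotype(sub)
  fit <- moderatedRegression(ph[[score]], strengths,
                             as.integer(ph$group == moderatorGroup),
                             nBoot = nBoot, ciLevel = ciLevel, seed = seed)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(score = score, moderatorGroup = moderatorGroup,
         coefficients = as.list(fit@coefficients),
         ci = list(lower = fit@ci[, 1], upper = fit@ci[, 2]),
         interactionP = fit@interactionP, nBoot = nBoot,
         ciLevel = ciLevel, seed = seed, nRedraws = fit@nRedraws),
    file.path(outDir, paste0("moderation_", score, ".json")),
    auto_unbox = TRUE, digits = NA)
  .writeStageLog(outDir, paste0("moderation_", score),
                 list(score = score, moderatorGroup = moderatorGroup,
                      nBoot = nBoot, seed = seed))
  invisible(fit)
}

#' Pipeline stage: full study-design contrast report
#'
#' Runs the study's NBS comparison set on a cohort directory — healthy
#' controls vs each patient group's pre scans (disruption, HC > patient),
#' HC vs post scans (residual disruption), and post vs pre within each
#' patient group (recovery/hyperconnectivity, post > pre) — and writes one
#' JSON summary.
#'
#' @param matDir cohort directory.
#' @param outDir results directory (`report.json`).
#' @param primaryP,nPerm,seed,alpha NBS settings.
#' @return named list of [NbsResult-class]s, invisibly.
#' @export
runReportStage <- function(matDir, outDir, primaryP = 1e-4,
                           nPerm = 1000L, seed = 1L, alpha = 0.05) {
  cohort <- readCohort(matDir)
  ph <- phenotype(cohort)
  patientGroups <- setdiff(unique(ph$group), "HC")
  results <- list()
  contrasts <- list()
  addContrast <- function(name, A, B, tail) {
    if (ncol(A) < 2L || ncol(B) < 2L) return(NULL)
    res <- nbsTest(A, B, tail = tail, primaryP = primaryP, nPerm = nPerm,
                   seed = seed, regionLabels = regionLabels(cohort))
    results[[name]] <<- res
    sm <- nbsSummary(res)
    contrasts[[name]] <<- list(
      tail = tail,
      nSignificant = sum(sm$correctedP < alpha),
      components = lapply(seq_len(nrow(sm)), function(k) {
        as.list(sm[k, c("edges", "nodes", "correctedP")])
      }))
  }
  hcPre <- edgeMatrix(subsetCohort(cohort, "HC"))
  for (g in patientGroups) {
    pre <- edgeMatrix(subsetCohort(cohort, g, "pre"))
    addContrast(paste0("HC_gt_", g, "_pre"), hcPre, pre, "greater")
    post <- tryCatch(edgeMatrix(subsetCohort(cohort, g, "post")),
                     error = function(e) NULL)
    if (!is.null(post) && ncol(post) >= 2L) {
      addContrast(paste0("HC_gt_", g, "_post"), hcPre, post, "greater")
      addContrast(paste0(g, "_post_gt_pre"), post, pre, "greater")
    }
  }
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(primaryP = primaryP, nPerm = nPerm, seed = seed, alpha = alpha,
         contrasts = contrasts),
    file.path(outDir, "report.json"), auto_unbox = TRUE, digits = NA)
  .writeStageLog(outDir, "report",
                 list(primaryP = primaryP, nPerm = nPerm, seed = seed))
  invisible(results)
}
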