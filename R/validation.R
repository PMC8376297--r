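#' Brute-force connected components (reference implementation)
#'
#' Independent depth-first-search component finder over an explicit
#' adjacency list, used to cross-check the graph-library route taken by
#' [suprathresholdComponents()]. Returns the same structure: components
#' with at least one edge, sorted by edge count descending.
#'
#' @param pairs 2-column matrix of edges (region index pairs).
#' @param nRegions region universe size.
#' @return list of components: each list(edges = EdgeSet, nodes, size).
#' @export
bruteForceComponents <- function(pairs, nRegions) {
  if (!nrow(pairs)) return(list())
  adj <- vector("list", nRegions)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  comp <- integer(nRegions)
  cur <- 0L
  for (start in sort(unique(as.integer(pairs)))) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    while (length(stack)) {                 # iterative DFS
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (comp[v] != 0L) next
      comp[v] <- cur
      stack <- c(stack, adj[[v]][comp[adj[[v]]] == 0L])
    }
  }
  edgeComp <- comp[pairs[, 1]]
  comps <- lapply(split(seq_len(nrow(pairs)), edgeComp), function(rows) {
    es <- EdgeSet(pairs[rows, , drop = FALSE], nRegions)
    list(edges = es, nodes = edgeNodes(es), size = length(rows))
  })
  comps <- unname(comps)
  comps[order(vapply(comps, `[[`, 0, "size"), decreasing = TRUE)]
}

# canonical fingerprint of a component decomposition: sorted list of
# sorted edge-index vectors
.componentFingerprint <- function(comps, nRegions) {
  sets <- lapply(comps, function(co) sort(edgeIndices(co$edges)))
  sets[order(vapply(sets, function(s) paste(s, collapse = ","), ""))]
}

#' Component-finder agreement over random graphs
#'
#' Generates random graphs and compares the component decomposition from
#' [suprathresholdComponents()]'s graph route against the brute-force DFS
#' reference.
#'
#' @param nGraphs number of random graphs (default 1000).
#' @param maxNodes node-count ceiling per graph (default 12).
#' @param seed RNG seed.
#' @return fraction of graphs with identical decompositions (1 = perfect).
#' @export
componentOracleStudy <- function(nGraphs = 1000L, maxNodes = 12L,
                                 seed = 1L) {
  set.seed(seed)
  agree <- 0L
  for (g in seq_len(nGraphs)) {
    n <- sample(3:maxNodes, 1L)
    density <- stats::runif(1, 0.05, 0.5)
    map <- edgeIndexMap(n)
    keep <- stats::runif(nrow(map)) < density
    pairs <- map[keep, , drop = FALSE]
    a <- .componentsFromEdges(pairs, n)
    b <- bruteForceComponents(pairs, n)
    if (identical(.componentFingerprint(a, n),
                  .componentFingerprint(b, n))) {
      agree <- agree + 1L
    }
  }
  agree / nGraphs
}

# small two-group config used by the simulation studies
.twoGroupConfig <- function(nRegions, groupSize, deltaZ, noiseSdZ, seed,
                            disruptedSize = 17L, ...) {
  simulationConfig(
    nRegions = nRegions,
    groupSizes = c(HC = groupSize, patient = groupSize),
    postSizes = integer(), paired = FALSE,
    disruptedSize = disruptedSize, deltaZ = deltaZ,
    hyperDeltaZ = 0, noiseSdZ = noiseSdZ, seed = seed, ...)
}

#' Familywise type-I error of the NBS under the null
#'
#' Repeatedly simulates two groups from one distribution (no planted
#' difference), runs the full NBS, and reports the fraction of simulations
#' in which any component reaches corrected significance.
#'
#' @param nSims simulated datasets (default 200).
#' @param nRegions,groupSize cohort geometry (default 50 regions, 20 + 20).
#' @param primaryP primary threshold (default 1e-2: at desk-scale group
#'   sizes the conventional 1e-4 leaves no suprathreshold edges at all,
#'   which would make the calibration vacuous).
#' @param nPerm permutations per simulation (default 200).
#' @param alpha corrected level scored (default 0.05).
#' @param seed root seed.
#' @return list(rejectionRate, rejections, nSims).
#' @export
nbsTypeIStudy <- function(nSims = 200L, nRegions = 50L, groupSize = 20L,
                          primaryP = 1e-2, nPerm = 200L, alpha = 0.05,
                          seed = 1L) {
  rejections <- 0L
  for (s in seq_len(nSims)) {
    cfg <- .twoGroupConfig(nRegions, groupSize, deltaZ = 0, noiseSdZ = 0.1,
                           seed = .deriveSeed(seed, 1009, s))
    cohort <- simulateConnectomes(cfg)
    ph <- phenotype(cohort)
    res <- nbsTest(edgeMatrix(cohort)[, ph$group == "HC"],
                   edgeMatrix(cohort)[, ph$group == "patient"],
                   tail = "greater", primaryP = primaryP, nPerm = nPerm,
                   seed = .deriveSeed(seed, 2003, s))
    if (length(res@correctedP) && any(res@correctedP < alpha)) {
      rejections <- rejections + 1L
    }
  }
  list(rejectionRate = rejections / nSims, rejections = rejections,
       nSims = nSims)
}

#' Planted-component recovery of the NBS
#'
#' Plants a connected subnetwork lowered by `deltaZ` in one group and
#' scores how well the largest detected component recovers it: edge-level
#' sensitivity, extra-edge fraction, and corrected p.
#'
#' @param nSeeds independent cohorts (default 50).
#' @param nRegions,groupSize cohort geometry (default 116 regions,
#'   30 + 30).
#' @param nEdgesPlanted planted component size (default 17 edges).
#' @param deltaZ,noiseSdZ effect and noise in Fisher-z units (0.8, 0.1).
#' @param nPerm permutations (default 500).
#' @param seed root seed.
#' @return list with per-seed `sensitivity`, `extraFraction`,
#'   `correctedP`, and `successes` = count of seeds with sensitivity >=
#'   0.9, extra fraction <= 0.1 and corrected p <= 0.01.
#' @export
nbsRecoveryStudy <- function(nSeeds = 50L, nRegions = 116L, groupSize = 30L,
                             nEdgesPlanted = 17L, deltaZ = 0.8,
                             noiseSdZ = 0.1, nPerm = 500L, seed = 1L) {
  sens <- extra <- pcor <- numeric(nSeeds)
  for (s in seq_len(nSeeds)) {
    cfg <- .twoGroupConfig(nRegions, groupSize, deltaZ = deltaZ,
                           noiseSdZ = noiseSdZ,
                           disruptedSize = nEdgesPlanted,
                           seed = .deriveSeed(seed, 3001, s))
    cohort <- simulateConnectomes(cfg)
    planted <- edgeIndices(cohortTruth(cohort)$disruptedEdges)
    ph <- phenotype(cohort)
    res <- nbsTest(edgeMatrix(cohort)[, ph$group == "HC"],
                   edgeMatrix(cohort)[, ph$group == "patient"],
                   tail = "greater", nPerm = nPerm,
                   seed = .deriveSeed(seed, 4001, s))
    if (!length(res@components)) {
      sens[s] <- 0; extra[s] <- 0; pcor[s] <- 1
      next
    }
    found <- edgeIndices(res@components[[1]]$edges)
    sens[s] <- length(intersect(found, planted)) / length(planted)
    extra[s] <- length(setdiff(found, planted)) / length(planted)
    pcor[s] <- res@correctedP[1]
  }
  ok <- sens >= 0.9 & extra <= 0.1 & pcor <= 0.01
  list(sensitivity = sens, extraFraction = extra, correctedP = pcor,
       successes = sum(ok), nSeeds = nSeeds)
}

# one healthy-control cohort with behavior at a target generator R^2;
# r2 = NULL means fully noiseless (no edge noise, no score noise), so the
# scores are an exact linear function of the planted network strength
.hcBehaviorCohort <- function(n, nRegions, r2, seed,
                              couplingBeta = 12) {
  edgeNoise <- if (is.null(r2)) 0 else 0.1
  cfg <- simulationConfig(
    nRegions = nRegions, groupSizes = c(HC = n), postSizes = integer(),
    paired = FALSE, hyperDeltaZ = 0, couplingBeta = couplingBeta,
    noiseSdZ = edgeNoise, seed = seed)
  cohort <- simulateConnectomes(cfg)
  s <- networkStrength(cohort, cfg@pmnEdges)
  noiseSd <- if (is.null(r2)) 0 else
    behaviorNoiseForR2(s, couplingBeta, r2)
  cfg2 <- simulationConfig(
    nRegions = nRegions, groupSizes = c(HC = n), postSizes = integer(),
    paired = FALSE, hyperDeltaZ = 0, couplingBeta = couplingBeta,
    noiseSdZ = edgeNoise, behaviorNoiseSd = noiseSd, seed = seed)
  list(cohort = simulateBehavior(cohort, cfg2), config = cfg2)
}

#' CPM null calibration: score-shuffled cross-validation
#'
#' Builds one healthy cohort, then repeatedly shuffles the behavioral
#' scores relative to the connectomes and runs the full cross-validated
#' CPM, collecting the out-of-fold predicted-observed correlation.
#'
#' @param nShuffles shuffled runs (default 100).
#' @param n,nRegions cohort geometry (default 32 subjects, 116 regions).
#' @param k,thresholdP CPM settings (5 folds, p < 0.01).
#' @param seed root seed.
#' @return list(meanR, r) with the per-shuffle correlations.
#' @export
cpmNullStudy <- function(nShuffles = 100L, n = 32L, nRegions = 116L,
                         k = 5L, thresholdP = 0.01, seed = 1L) {
  hc <- .hcBehaviorCohort(n, nRegions, r2 = 0.5,
                          seed = .deriveSeed(seed, 5003, 1L))
  X <- edgeMatrix(hc$cohort)
  scores <- phenotype(hc$cohort)$DST
  r <- numeric(nShuffles)
  for (s in seq_len(nShuffles)) {
    set.seed(.deriveSeed(seed, 6007, s))
    shuffled <- sample(scores)
    res <- suppressMessages(suppressWarnings(
      cpmCrossval(X, shuffled, k = k, thresholdP = thresholdP,
                  tail = "positive",
                  seed = .deriveSeed(seed, 7001, s))))
    r[s] <- res@rPredObs
  }
  list(meanR = mean(r), r = r)
}

#' CPM signal recovery on cohorts with planted brain-behavior coupling
#'
#' @param nSeeds independent cohorts (default 50).
#' @param n,nRegions cohort geometry (default 32 subjects, 116 regions).
#' @param r2 generator proportion of score variance explained by network
#'   strength (default 0.5); `NULL` gives noiseless coupling.
#' @param k,thresholdP CPM settings.
#' @param seed root seed.
#' @return list(meanR, r).
#' @export
cpmRecoveryStudy <- function(nSeeds = 50L, n = 32L, nRegions = 116L,
                             r2 = 0.5, k = 5L, thresholdP = 0.01,
                             seed = 1L) {
  r <- numeric(nSeeds)
  for (s in seq_len(nSeeds)) {
    hc <- .hcBehaviorCohort(n, nRegions, r2,
                            seed = .deriveSeed(seed, 8009, s))
    res <- suppressMessages(suppressWarnings(
      cpmCrossval(hc$cohort, "DST", k = k, thresholdP = thresholdP,
                  tail = "positive",
                  seed = .deriveSeed(seed, 9001, s))))
    r[s] <- res@rPredObs
  }
  list(meanR = mean(r), r = r)
}

#' Coverage and bias of the moderated-regression bootstrap CI
#'
#' Simulates patient cohorts with a known group-by-strength interaction
#' `gamma`, fits [moderatedRegression()] with bias-corrected bootstrap
#' CIs, and reports interaction-CI coverage of the true value and the mean
#' point estimate.
#'
#' @param nSims simulated datasets (default 200).
#' @param gamma true interaction coefficient (default 0).
#' @param nRegions regions (default 60; the moderation analysis only needs
#'   strengths, so a compact connectome suffices).
#' @param groupSizes two patient groups (default 23 non-OHE + 13 OHE,
#'   n = 36).
#' @param behaviorNoiseSd score noise (default 1).
#' @param nBoot bootstrap resamples per fit (default 1000).
#' @param ciLevel nominal coverage (default 0.95).
#' @param seed root seed.
#' @return list(coverage, meanEstimate, estimates, covered).
#' @export
moderationCoverageStudy <- function(nSims = 200L, gamma = 0,
                                    nRegions = 60L,
                                    groupSizes = c(nonOHE = 23L, OHE = 13L),
                                    behaviorNoiseSd = 1,
                                    nBoot = 1000L, ciLevel = 0.95,
                                    seed = 1L) {
  est <- numeric(nSims)
  covered <- logical(nSims)
  for (s in seq_len(nSims)) {
    cfg <- simulationConfig(
      nRegions = nRegions, groupSizes = groupSizes,
      postSizes = integer(), paired = FALSE, deltaZ = 0, hyperDeltaZ = 0,
      moderationGamma = gamma, behaviorNoiseSd = behaviorNoiseSd,
      seed = .deriveSeed(seed, 10007, s))
    cohort <- simulateBehavior(simulateConnectomes(cfg), cfg,
                               moderatorGroup = "OHE")
    ph <- phenotype(cohort)
    strengths <- networkStrength(cohort, cfg@pmnEdges)
    fit <- moderatedRegression(
      ph$DST, strengths, as.integer(ph$group == "OHE"),
      nBoot = nBoot, ciLevel = ciLevel,
      seed = .deriveSeed(seed, 11003, s))
    est[s] <- fit@coefficients["interaction"]
    ci <- fit@ci["interaction", ]
    covered[s] <- ci[1] <= gamma && gamma <= ci[2]
  }
  list(coverage = mean(covered), meanEstimate = mean(est),
       estimates = est, covered = covered)
}
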