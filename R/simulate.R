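#' Plant a connected edge subnetwork
#'
#' Samples `nEdges` distinct upper-triangle edges whose induced subgraph is
#' connected, by growing a random spanning tree on a sampled node subset and
#' topping it up with random within-subset edges. Connected planted sets are
#' what the component-based group test is expected to recover.
#'
#' The node subset size is chosen so the planted graph is sparse (roughly
#' tree-like, mirroring the 16-node/17-edge scale of empirically reported
#' disrupted networks) unless `nEdges` forces a denser graph.
#'
#' @param nRegions region universe size.
#' @param nEdges number of edges; at most N(N-1)/2.
#' @param rngSeed integer seed.
#' @param regionLabels optional labels for the result.
#' @return an [EdgeSet-class] of `nEdges` edges forming one connected
#'   component.
#' @examples
#' plantEdgeSet(116, 17, rngSeed = 1)
#' @export
plantEdgeSet <- function(nRegions, nEdges, rngSeed = 1L,
                         regionLabels = character()) {
  nRegions <- .checkCount(nRegions, "nRegions", min = 3L)
  nEdges <- .checkCount(nEdges, "nEdges", min = 1L)
  E <- nEdges(nRegions)
  if (nEdges > E) {
    stop("nEdges = ", nEdges, " exceeds the ", E,
         " possible edges on ", nRegions, " regions")
  }
  mMin <- ceiling((1 + sqrt(1 + 8 * nEdges)) / 2)   # capacity bound
  m <- min(nRegions, max(mMin, nEdges - 1L, 2L))
  set.seed(rngSeed)
  nodes <- sample.int(nRegions, m)
  # random tree: node k attaches to a uniformly chosen earlier node
  tree <- if (m > 1L) {
    cbind(nodes[vapply(2:m, function(k) sample.int(k - 1L, 1L), 1L)],
          nodes[2:m])
  } else matrix(integer(), 0L, 2L)
  pairs <- tree[seq_len(min(nrow(tree), nEdges)), , drop = FALSE]
  extra <- nEdges - nrow(pairs)
  if (extra > 0L) {
    allIdx <- utils::combn(sort(nodes), 2L)
    allKeys <- edgeIndex(allIdx[1, ], allIdx[2, ], nRegions)
    used <- edgeIndex(pmin(pairs[, 1], pairs[, 2]),
                      pmax(pairs[, 1], pairs[, 2]), nRegions)
    free <- which(!allKeys %in% used)
    pick <- free[sample.int(length(free), extra)]
    pairs <- rbind(pairs, t(allIdx[, pick, drop = FALSE]))
  }
  EdgeSet(pairs, nRegions, regionLabels)
}

#' Simulation settings for synthetic cohorts
#'
#' Defines the cohort structure and planted effects of the synthetic
#' connectome generator. Defaults emulate the study design the package
#' targets: three groups (32 healthy controls, 36 non-OHE and 28 OHE
#' cirrhotic patients), paired pre/post sessions for patients with 23/13
#' post-session completers, a 17-edge disrupted subnetwork lowered by
#' `deltaZ` in patient pre scans, a 19-edge hyperconnectivity subnetwork
#' raised in OHE post scans, and an 18-edge behavior-coupled subnetwork
#' whose mean strength drives the DST (positively) and NCT (negatively)
#' psychomotor scores, with a group-moderated slope.
#'
#' @param nRegions regions (default 116).
#' @param groupSizes named integer vector of per-group subject counts; the
#'   group named `"HC"` (or the first group) is the healthy reference, all
#'   other groups are patients with a pre session.
#' @param postSizes named counts of patients with a post session (subset of
#'   each patient group); ignored when `paired = FALSE`.
#' @param paired give patients paired pre/post sessions.
#' @param timepoints,samplingInterval time-series mode dimensions (volumes
#'   after discard, seconds per volume).
#' @param disruptedEdges,hyperEdges,pmnEdges planted [EdgeSet-class]s; when
#'   `NULL` they are planted from the seed with sizes `disruptedSize`,
#'   `hyperSize`, `pmnSize` and made mutually disjoint (re-planted with a
#'   shifted sub-seed on overlap).
#' @param disruptedSize,hyperSize,pmnSize default planted-set sizes (17, 19,
#'   18 edges).
#' @param deltaZ Fisher-z units subtracted on `disruptedEdges` in patient
#'   pre scans.
#' @param hyperDeltaZ Fisher-z units added on `hyperEdges` in OHE post
#'   scans (0 disables the hyperconnectivity scenario).
#' @param couplingBeta behavior units per unit network strength (DST slope;
#'   the NCT slope is its negative).
#' @param subjectStrengthSd SD of the per-subject latent strength factor
#'   added uniformly on `pmnEdges` — the individual differences in network
#'   strength that behavior couples to.
#' @param noiseSdZ i.i.d. edge noise SD (Fisher-z units).
#' @param behaviorNoiseSd score noise SD (behavior units).
#' @param moderationGamma group-by-strength interaction coefficient
#'   (behavior units per unit strength, applied for the moderator group).
#' @param baseMeanZ,baseSdZ distribution of the shared base connectome.
#' @param interceptDST,interceptNCT score intercepts at mean strength.
#' @param seed root RNG seed; per-subject streams are derived by counter so
#'   growing the cohort does not reshuffle existing subjects.
#' @return a validated [SimulationConfig-class].
#' @export
simulationConfig <- function(nRegions = 116L,
                             groupSizes = c(HC = 32L, nonOHE = 36L, OHE = 28L),
                             postSizes = c(nonOHE = 23L, OHE = 13L),
                             paired = TRUE,
                             timepoints = 190L, samplingInterval = 2.5,
                             disruptedEdges = NULL, disruptedSize = 17L,
                             deltaZ = 0.8,
                             hyperEdges = NULL, hyperSize = 19L,
                             hyperDeltaZ = 0.8,
                             pmnEdges = NULL, pmnSize = 18L,
                             couplingBeta = 12, subjectStrengthSd = 0.15,
                             noiseSdZ = 0.1, behaviorNoiseSd = 1.8,
                             moderationGamma = 12,
                             baseMeanZ = 0.25, baseSdZ = 0.15,
                             interceptDST = 47.8, interceptNCT = 40.4,
                             seed = 1L) {
  nRegions <- .checkCount(nRegions, "nRegions", min = 3L)
  groupSizes <- vapply(groupSizes, .checkCount, 0L, what = "group size",
                       min = 2L)
  if (!paired) postSizes <- integer()
  postSizes <- vapply(postSizes, .checkCount, 0L, what = "post size", min = 0L)
  seed <- .checkCount(seed, "seed")
  planted <- list(disrupted = disruptedEdges, hyper = hyperEdges,
                  pmn = pmnEdges)
  sizes <- c(disrupted = disruptedSize, hyper = hyperSize, pmn = pmnSize)
  sub <- 101L
  for (nm in names(planted)) {
    if (is.null(planted[[nm]])) {
      repeat {
        cand <- plantEdgeSet(nRegions, sizes[[nm]],
                             rngSeed = .deriveSeed(seed, 131, sub))
        sub <- sub + 1L
        others <- unlist(lapply(planted[names(planted) != nm],
                                function(e) if (!is.null(e)) edgeIndices(e)))
        if (!any(edgeIndices(cand) %in% others)) break
      }
      planted[[nm]] <- cand
    }
  }
  new("SimulationConfig",
      nRegions = nRegions, groupSizes = groupSizes,
      postSizes = postSizes, paired = paired,
      timepoints = as.integer(timepoints),
      samplingInterval = samplingInterval,
      disruptedEdges = planted$disrupted, deltaZ = deltaZ,
      hyperEdges = planted$hyper, hyperDeltaZ = hyperDeltaZ,
      pmnEdges = planted$pmn, couplingBeta = couplingBeta,
      subjectStrengthSd = subjectStrengthSd, noiseSdZ = noiseSdZ,
      behaviorNoiseSd = behaviorNoiseSd, moderationGamma = moderationGamma,
      baseMeanZ = baseMeanZ, baseSdZ = baseSdZ,
      interceptDST = interceptDST, interceptNCT = interceptNCT,
      seed = seed)
}

# deterministic derived seed: overflow-safe 32-bit reduction
.deriveSeed <- function(seed, mult, offset) {
  as.integer((as.numeric(seed) * as.numeric(mult) + as.numeric(offset)) %%
               2147483629)
}

# deterministic per-subject stream seed, independent of cohort size
.subjectSeed <- function(rootSeed, counter) {
  .deriveSeed(counter, 48271, rootSeed)
}

# phenotype skeleton implied by a config: one row per subject-session
.cohortDesign <- function(config) {
  groups <- names(config@groupSizes)
  reference <- if ("HC" %in% groups) "HC" else groups[1]
  rows <- list()
  counter <- 0L
  for (g in groups) {
    nPost <- if (g != reference && config@paired &&
                 g %in% names(config@postSizes)) {
      config@postSizes[[g]]
    } else 0L
    for (k in seq_len(config@groupSizes[[g]])) {
      counter <- counter + 1L
      id <- sprintf("%s%03d", g, k)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = id, group = g, session = "pre", counter = counter)
      if (k <= nPost) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject = id, group = g, session = "post", counter = counter)
      }
    }
  }
  design <- do.call(rbind, rows)
  design$reference <- reference
  design
}

# per-session target z vector (before edge noise) and the noise draw
.subjectEdgeVector <- function(config, baseZ, design, row, E) {
  g <- design$group[row]; sess <- design$session[row]
  reference <- design$reference[1]
  set.seed(.subjectSeed(config@seed, design$counter[row]))
  u <- stats::rnorm(1L, 0, config@subjectStrengthSd)
  noisePre <- stats::rnorm(E) * config@noiseSdZ
  noisePost <- stats::rnorm(E) * config@noiseSdZ
  z <- baseZ
  idxPmn <- edgeIndices(config@pmnEdges)
  z[idxPmn] <- z[idxPmn] + u
  if (g != reference && sess == "pre") {
    idx <- edgeIndices(config@disruptedEdges)
    z[idx] <- z[idx] - config@deltaZ
  }
  if (g == "OHE" && sess == "post" && config@hyperDeltaZ != 0) {
    idx <- edgeIndices(config@hyperEdges)
    z[idx] <- z[idx] + config@hyperDeltaZ
  }
  list(target = z,
       observed = z + if (sess == "pre") noisePre else noisePost,
       strengthFactor = u)
}

#' Simulate a cohort of connectomes (direct-z mode)
#'
#' Draws each subject-session's Fisher-z edge vector as a shared base
#' connectome plus group/session offsets on the planted edge sets, a
#' per-subject latent strength factor on the behavior-coupled set, and
#' i.i.d. edge noise. Ground truth (planted sets and coefficients) is
#' recorded in the cohort metadata.
#'
#' @param config a [simulationConfig()].
#' @param regionLabels optional region names; defaults to
#'   [aalRegionLabels()] when `nRegions == 116`.
#' @return a [ConnectomeCohort-class] without behavior scores (add them
#'   with [simulateBehavior()]).
#' @export
simulateConnectomes <- function(config, regionLabels = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  E <- nEdges(config@nRegions)
  if (is.null(regionLabels) && config@nRegions == 116L) {
    regionLabels <- aalRegionLabels()
  }
  set.seed(config@seed)
  baseZ <- stats::rnorm(E, config@baseMeanZ, config@baseSdZ)
  design <- .cohortDesign(config)
  z <- matrix(NA_real_, E, nrow(design))
  strengthFactor <- numeric(nrow(design))
  for (row in seq_len(nrow(design))) {
    sub <- .subjectEdgeVector(config, baseZ, design, row, E)
    z[, row] <- sub$observed
    strengthFactor[row] <- sub$strengthFactor
  }
  truth <- list(
    disruptedEdges = config@disruptedEdges, deltaZ = config@deltaZ,
    hyperEdges = config@hyperEdges, hyperDeltaZ = config@hyperDeltaZ,
    pmnEdges = config@pmnEdges, couplingBeta = config@couplingBeta,
    moderationGamma = config@moderationGamma,
    subjectStrengthSd = config@subjectStrengthSd,
    referenceGroup = design$reference[1], config = config
  )
  ConnectomeCohort(z, design[, c("subject", "group", "session")],
                   nRegions = config@nRegions, regionLabels = regionLabels,
                   truth = truth)
}

#' Attach simulated behavior scores to a cohort
#'
#' Generates the two psychomotor scores from each subject-session's
#' realized strength on the behavior-coupled edge set `s` (centered at the
#' cohort mean): `DST = interceptDST + beta * s + gamma * g * s + noise` and
#' `NCT = interceptNCT - beta * s - gamma * g * s + noise`, where `g`
#' indicates the moderator group. The negative NCT coupling encodes the
#' convention that stronger connectivity means faster (better) completion
#' times.
#'
#' @param cohort a [ConnectomeCohort-class].
#' @param config the [simulationConfig()] that generated it.
#' @param moderatorGroup group whose brain-behavior slope is shifted by
#'   `moderationGamma`; default `"OHE"` when present, else no moderation.
#' @return the cohort with `NCT` and `DST` filled in `colData` and the
#'   behavior coefficients appended to the truth.
#' @export
simulateBehavior <- function(cohort, config, moderatorGroup = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  if (length(config@pmnEdges) == 0L) {
    stop("pmnEdges is empty: no edge set to couple behavior to")
  }
  ph <- phenotype(cohort)
  if (is.null(moderatorGroup)) {
    moderatorGroup <- if ("OHE" %in% ph$group) "OHE" else NA_character_
  }
  s <- networkStrength(cohort, config@pmnEdges)
  sc <- s - mean(s)
  g <- as.numeric(!is.na(moderatorGroup) & ph$group == moderatorGroup)
  set.seed(.subjectSeed(config@seed, 999983L))
  n <- ncol(cohort)
  eDst <- stats::rnorm(n) * config@behaviorNoiseSd
  eNct <- stats::rnorm(n) * config@behaviorNoiseSd
  beta <- config@couplingBeta
  gamma <- config@moderationGamma
  dst <- config@interceptDST + beta * sc + gamma * g * sc + eDst
  nct <- config@interceptNCT - beta * sc - gamma * g * sc + eNct
  colData(cohort)$DST <- dst
  colData(cohort)$NCT <- nct
  md <- metadata(cohort)
  md$truth$behavior <- list(moderatorGroup = moderatorGroup,
                            couplingBeta = beta, moderationGamma = gamma,
                            strengths = s)
  metadata(cohort) <- md
  cohort
}

#' Score-noise SD achieving a target generator R-squared
#'
#' For scores generated as `beta * strength + noise`, returns the noise SD
#' for which the strength term explains a fraction `r2` of score variance,
#' given the realized strengths.
#'
#' @param strengths numeric vector of realized network strengths.
#' @param beta coupling coefficient.
#' @param r2 target proportion of variance explained (0 < r2 < 1).
#' @export
behaviorNoiseForR2 <- function(strengths, beta, r2) {
  if (r2 <= 0 || r2 >= 1) stop("r2 must lie strictly between 0 and 1")
  abs(beta) * stats::sd(strengths) * sqrt((1 - r2) / r2)
}
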