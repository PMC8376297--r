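#' @import methods
#' @importFrom S4Vectors DataFrame metadata SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' EdgeSet: a set of unordered region pairs
#'
#' A set of edges (unordered region pairs) over a fixed region universe,
#' stored as 1-based index pairs with i < j. Used for planted subnetworks,
#' suprathreshold components, CPM tails and consensus networks.
#'
#' @slot pairs integer matrix, one row per edge, columns `i`, `j` (i < j).
#' @slot nRegions size of the region universe.
#' @slot regionLabels region names (length nRegions, possibly empty).
#' @slot provenance optional per-edge tag (e.g. "positive" / "negative" /
#'   "both" after [combineNetworks()]); length 0 or nrow(pairs).
#' @export
setClass("EdgeSet",
  representation(
    pairs = "matrix",
    nRegions = "integer",
    regionLabels = "character",
    provenance = "character"
  )
)

setValidity("EdgeSet", function(object) {
  p <- object@pairs
  if (!is.numeric(p) || ncol(p) != 2L) return("pairs must be a 2-column matrix")
  if (nrow(p)) {
    if (any(p != round(p))) return("pairs must be integer region indices")
    if (any(p[, 1] >= p[, 2])) return("pairs must satisfy i < j")
    if (any(p < 1) || any(p > object@nRegions)) {
      return("pair indices out of 1..nRegions")
    }
    if (anyDuplicated(edgeIndex(p[, 1], p[, 2], object@nRegions))) {
      return("duplicate edges")
    }
  }
  if (length(object@regionLabels) &&
      length(object@regionLabels) != object@nRegions) {
    return("regionLabels must have length nRegions")
  }
  if (length(object@provenance) &&
      length(object@provenance) != nrow(p)) {
    return("provenance must have one entry per edge")
  }
  TRUE
})

#' Edge-wise two-sample test map
#'
#' Per-edge t statistics and one-tailed p values over the canonical edge
#' ordering, together with the edge-inclusion mask. Excluded edges carry
#' `NA` statistics (the sentinel).
#'
#' @slot t,p length-E numeric vectors (NA where not included).
#' @slot tail "greater" (A > B) or "less" (A < B).
#' @slot df degrees of freedom (length 1 for the pooled test, length E for
#'   Welch).
#' @slot included length-E logical inclusion mask.
#' @slot nRegions region count N with E = N(N-1)/2.
#' @export
setClass("EdgeTestMap",
  representation(
    t = "numeric", p = "numeric", tail = "character",
    df = "numeric", included = "logical", nRegions = "integer"
  )
)

setValidity("EdgeTestMap", function(object) {
  E <- nEdges(object@nRegions)
  if (length(object@t) != E || length(object@p) != E ||
      length(object@included) != E) {
    return("t, p and included must have length N(N-1)/2")
  }
  pin <- object@p[object@included]
  if (any(!is.na(pin) & (pin < 0 | pin > 1))) return("p values outside [0,1]")
  if (any(!is.na(object@p[!object@included]))) {
    return("excluded edges must carry the NA sentinel")
  }
  if (!object@tail %in% c("greater", "less")) {
    return("tail must be 'greater' or 'less'")
  }
  TRUE
})

#' Network-based statistic result
#'
#' @slot components list of suprathreshold connected components (largest
#'   first); each is a list with `edges` (EdgeSet), `nodes` (integer vector)
#'   and `size` (edge count).
#' @slot correctedP numeric, one familywise-corrected p per component.
#' @slot nullMaxSizes permutation null distribution of the maximal component
#'   size (edges).
#' @slot tests the observed [EdgeTestMap].
#' @slot primaryP primary (edge-level) threshold.
#' @slot nPerm,seed permutation count and RNG seed.
#' @slot tail test direction.
#' @export
setClass("NbsResult",
  representation(
    components = "list", correctedP = "numeric", nullMaxSizes = "numeric",
    tests = "EdgeTestMap", primaryP = "numeric", nPerm = "integer",
    seed = "integer", tail = "character"
  )
)

setValidity("NbsResult", function(object) {
  if (length(object@correctedP) != length(object@components)) {
    return("one corrected p per component required")
  }
  if (length(object@correctedP) &&
      (any(object@correctedP <= 0) || any(object@correctedP > 1))) {
    return("corrected p must lie in (0, 1]")
  }
  sz <- vapply(object@components, function(co) co$size, numeric(1))
  ne <- vapply(object@components, function(co) nrow(edgePairs(co$edges)),
               numeric(1))
  if (any(sz != ne)) return("component size must equal its edge count")
  if (is.unsorted(rev(sz))) return("components must be sorted by size, descending")
  TRUE
})

#' CPM tail selection
#'
#' Edges whose connectivity correlates with a behavioral score at
#' `p < thresholdP`, split by correlation sign.
#'
#' @slot positive,negative [EdgeSet]s of the positive / negative tails.
#' @slot r,p per-edge correlation and two-tailed p over all E edges (NA for
#'   constant edges).
#' @slot thresholdP selection threshold.
#' @export
setClass("TailSelection",
  representation(
    positive = "EdgeSet", negative = "EdgeSet",
    r = "numeric", p = "numeric", thresholdP = "numeric"
  )
)

setValidity("TailSelection", function(object) {
  ip <- edgeIndices(object@positive)
  im <- edgeIndices(object@negative)
  if (length(intersect(ip, im))) return("tails must be disjoint")
  TRUE
})

#' Connectome predictive mapping result
#'
#' @slot folds list (one per fold) with train/test column indices, the
#'   fold's [TailSelection], and slope/intercept of the strength-score fit.
#' @slot predictions out-of-fold predicted scores (one per subject).
#' @slot observed observed scores.
#' @slot rPredObs,pPredObs predicted-vs-observed Pearson r and two-tailed p.
#' @slot consensusPositive,consensusNegative edges selected in every fold.
#' @slot tail which tail network drove prediction ("positive"/"negative").
#' @slot k,thresholdP,seed cross-validation parameters.
#' @export
setClass("CpmResult",
  representation(
    folds = "list", predictions = "numeric", observed = "numeric",
    rPredObs = "numeric", pPredObs = "numeric",
    consensusPositive = "EdgeSet", consensusNegative = "EdgeSet",
    tail = "character", k = "integer", thresholdP = "numeric",
    seed = "integer"
  )
)

setValidity("CpmResult", function(object) {
  n <- length(object@observed)
  test <- sort(unlist(lapply(object@folds, `[[`, "test")))
  if (!identical(test, seq_len(n))) {
    return("every subject must appear in exactly one test fold")
  }
  for (f in object@folds) {
    sel <- f$selection
    if (!all(edgeIndices(object@consensusPositive) %in%
             edgeIndices(sel@positive)) ||
        !all(edgeIndices(object@consensusNegative) %in%
             edgeIndices(sel@negative))) {
      return("consensus edges must be selected in every fold")
    }
  }
  TRUE
})

#' Moderated regression result
#'
#' OLS fit of score ~ strength * moderator with bias-corrected percentile
#' bootstrap confidence intervals for the unstandardized coefficients.
#'
#' @slot coefficients named numeric: intercept, strength, moderator,
#'   interaction.
#' @slot ci 4 x 2 matrix of (lower, upper) per coefficient.
#' @slot interactionP OLS t-test p value of the interaction term.
#' @slot nBoot,ciLevel,seed bootstrap parameters.
#' @slot nRedraws bootstrap resamples redrawn because one moderator level
#'   was absent.
#' @export
setClass("ModerationResult",
  representation(
    coefficients = "numeric", ci = "matrix", interactionP = "numeric",
    nBoot = "integer", ciLevel = "numeric", seed = "integer",
    nRedraws = "integer"
  )
)

setValidity("ModerationResult", function(object) {
  if (any(object@ci[, 1] > object@coefficients) ||
      any(object@ci[, 2] < object@coefficients)) {
    return("each CI must bracket its point estimate")
  }
  TRUE
})

#' Synthetic cohort simulation settings
#'
#' See [simulationConfig()] for field semantics and defaults.
#' @export
setClass("SimulationConfig",
  representation(
    nRegions = "integer", groupSizes = "integer", postSizes = "integer",
    paired = "logical", timepoints = "integer", samplingInterval = "numeric",
    disruptedEdges = "EdgeSet", deltaZ = "numeric",
    hyperEdges = "EdgeSet", hyperDeltaZ = "numeric",
    pmnEdges = "EdgeSet", couplingBeta = "numeric",
    subjectStrengthSd = "numeric", noiseSdZ = "numeric",
    behaviorNoiseSd = "numeric", moderationGamma = "numeric",
    baseMeanZ = "numeric", baseSdZ = "numeric",
    interceptDST = "numeric", interceptNCT = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  if (object@nRegions < 3L) return("nRegions must be >= 3")
  if (any(object@groupSizes < 2L)) return("all group sizes must be >= 2")
  if (is.null(names(object@groupSizes))) return("groupSizes must be named")
  if (length(object@postSizes) &&
      any(object@postSizes > object@groupSizes[names(object@postSizes)],
          na.rm = TRUE)) {
    return("postSizes cannot exceed the group sizes")
  }
  for (es in list(object@disruptedEdges, object@hyperEdges, object@pmnEdges)) {
    if (nrow(edgePairs(es)) && nRegions(es) != object@nRegions) {
      return("planted edge sets must live on the config's region universe")
    }
  }
  if (object@noiseSdZ < 0 || object@behaviorNoiseSd < 0 ||
      object@subjectStrengthSd < 0 || object@baseSdZ < 0) {
    return("noise SDs must be >= 0")
  }
  TRUE
})

#' Cohort of subject connectomes
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose single assay `"z"`
#' holds the Fisher-z edge matrix (E edges x S subject-sessions, canonical
#' upper-triangle edge order in rows), with the phenotype table (subject,
#' group, session, NCT, DST) in `colData` and the region universe plus any
#' simulation ground truth in `metadata`.
#' @export
setClass("ConnectomeCohort", contains = "SummarizedExperiment")

setValidity("ConnectomeCohort", function(object) {
  md <- metadata(object)
  if (is.null(md$nRegions)) return("metadata$nRegions is required")
  if (nrow(object) != nEdges(md$nRegions)) {
    return("assay must have N(N-1)/2 edge rows")
  }
  if (!"z" %in% SummarizedExperiment::assayNames(object)) {
    return("assay 'z' is required")
  }
  need <- c("subject", "group", "session")
  if (!all(need %in% colnames(colData(object)))) {
    return("colData must contain subject, group, session")
  }
  TRUE
})

#' Cohort of ROI time series
#'
#' Output of the time-series simulation mode: one T x N BOLD series per
#' subject-session plus the phenotype table; converted to a
#' [ConnectomeCohort] via [cohortFromTimeSeries()].
#'
#' @slot series named list of T x N matrices.
#' @slot phenotype data.frame with subject, group, session rows matching
#'   `series`.
#' @slot samplingInterval seconds between volumes.
#' @slot regionLabels region names.
#' @slot truth simulation ground truth (planted sets, coefficients,
#'   shrinkage factors).
#' @export
setClass("TimeSeriesCohort",
  representation(
    series = "list", phenotype = "data.frame", samplingInterval = "numeric",
    regionLabels = "character", truth = "list"
  )
)

setValidity("TimeSeriesCohort", function(object) {
  if (length(object@series) != nrow(object@phenotype)) {
    return("one series per phenotype row required")
  }
  TRUE
})
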