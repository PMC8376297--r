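# Pearson correlation of every edge row with a score vector, plus its
# two-tailed p from the t transform. Constant edges return NA.
.edgeScoreCor <- function(X, scores) {
  n <- length(scores)
  Xc <- X - rowMeans(X)
  s <- scores - mean(scores)
  den <- sqrt(rowSums(Xc^2) * sum(s^2))
  r <- drop(Xc %*% s) / den
  r[den == 0] <- NA_real_
  r <- pmin(pmax(r, -1), 1)
  t <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(t), df = n - 2, lower.tail = FALSE)
  p[abs(r) == 1] <- 0
  list(r = r, p = p)
}

#' Select behavior-correlated edges (CPM tails)
#'
#' Correlates every edge's Fisher-z values with a behavioral score across
#' subjects (equivalently, the simple per-edge regression of score on
#' edge), keeps edges with `p < thresholdP`, and splits them into a
#' positive tail (r > 0) and a negative tail (r < 0).
#'
#' @param train E x n edge matrix or [ConnectomeCohort-class] (n >= 4).
#' @param scores length-n behavioral scores with nonzero variance.
#' @param thresholdP selection threshold (default 0.01).
#' @param regionLabels labels for the tail edge sets.
#' @return a [TailSelection-class].
#' @export
selectEdges <- function(train, scores, thresholdP = 0.01,
                        regionLabels = character()) {
  if (is(train, "ConnectomeCohort")) {
    if (!length(regionLabels)) regionLabels <- regionLabels(train)
    train <- edgeMatrix(train)
  }
  n <- ncol(train)
  if (n < 4L) stop("need at least 4 training subjects")
  if (length(scores) != n) stop("scores must match the subject count")
  if (stats::sd(scores) == 0) stop("scores have zero variance")
  es <- .edgeScoreCor(train, scores)
  if (anyNA(es$r)) {
    message(sum(is.na(es$r)), " constant edge(s) skipped in selection")
  }
  nRegions <- .nRegionsFromEdges(nrow(train))
  hit <- !is.na(es$p) & es$p < thresholdP
  new("TailSelection",
      positive = edgeSetFromIndices(which(hit & es$r > 0), nRegions,
                                    regionLabels),
      negative = edgeSetFromIndices(which(hit & es$r < 0), nRegions,
                                    regionLabels),
      r = es$r, p = es$p, thresholdP = thresholdP)
}

setMethod("show", "TailSelection", function(object) {
  cat("TailSelection (p <", format(object@thresholdP), "):",
      length(object@positive), "positive,",
      length(object@negative), "negative edges\n")
})

#' @rdname networkStrength
#' @export
setMethod("networkStrength", "matrix", function(x, edges) {
  if (!length(edges)) stop("empty edge set: network strength is undefined")
  N <- nRegions(edges)
  if (nrow(x) == N && ncol(x) == N) {      # one subject's square z matrix
    p <- edgePairs(edges)
    return(mean(x[cbind(p[, 1], p[, 2])]))
  }
  if (nrow(x) != nEdges(N)) {
    stop("matrix is neither an NxN connectivity matrix nor an ExS edge ",
         "matrix for a ", N, "-region universe")
  }
  colMeans(x[edgeIndices(edges), , drop = FALSE])
})

#' @rdname networkStrength
#' @export
setMethod("networkStrength", "ConnectomeCohort", function(x, edges) {
  networkStrength(edgeMatrix(x), edges)
})

#' Connectome predictive mapping with k-fold cross-validation
#'
#' Randomly partitions subjects into k folds; per fold, selects
#' behavior-correlated edges on the training subjects only, summarizes each
#' training subject as the mean strength over the chosen tail, fits
#' `score = a * strength + b` by ordinary least squares, and predicts the
#' held-out subjects. Out-of-fold predictions are pooled and correlated
#' with the observed scores; consensus edges per tail are those selected in
#' every fold.
#'
#' @param cohort E x n edge matrix or [ConnectomeCohort-class].
#' @param scores length-n scores; for a cohort, a phenotype column name
#'   ("DST" or "NCT") is also accepted.
#' @param k fold count (default 5; `k = n` gives leave-one-out). Requires
#'   `2 <= k <= n` and at least 4 training subjects per fold.
#' @param thresholdP edge-selection threshold (default 0.01).
#' @param tail which tail's strength drives the prediction: "positive"
#'   (convention for DST-like scores where higher is better) or "negative"
#'   (NCT-like). A fold whose chosen tail is empty predicts the training
#'   mean score (with a warning).
#' @param seed RNG seed for the fold partition.
#' @param regionLabels labels for edge sets.
#' @return a [CpmResult-class].
#' @export
cpmCrossval <- function(cohort, scores, k = 5L, thresholdP = 0.01,
                        tail = c("positive", "negative"), seed = 1L,
                        regionLabels = character()) {
  tail <- match.arg(tail)
  if (is(cohort, "ConnectomeCohort")) {
    if (!length(regionLabels)) regionLabels <- regionLabels(cohort)
    if (is.character(scores) && length(scores) == 1L) {
      scores <- phenotype(cohort)[[scores]]
    }
    cohort <- edgeMatrix(cohort)
  }
  n <- ncol(cohort)
  k <- .checkCount(k, "k", min = 2L)
  if (k > n) stop("k cannot exceed the number of subjects")
  if (length(scores) != n) stop("scores must match the subject count")
  set.seed(.checkCount(seed, "seed"))
  foldOf <- sample(rep_len(seq_len(k), n))
  folds <- vector("list", k)
  predictions <- numeric(n)
  emptyFolds <- 0L
  for (f in seq_len(k)) {
    test <- which(foldOf == f)
    train <- which(foldOf != f)
    sel <- selectEdges(cohort[, train, drop = FALSE], scores[train],
                       thresholdP, regionLabels)
    edges <- slot(sel, tail)
    if (length(edges) == 0L) {
      emptyFolds <- emptyFolds + 1L
      slope <- 0; intercept <- mean(scores[train])
      predictions[test] <- intercept
    } else {
      sTrain <- networkStrength(cohort[, train, drop = FALSE], edges)
      fit <- stats::lm.fit(cbind(1, sTrain), scores[train])
      intercept <- fit$coefficients[1]; slope <- fit$coefficients[2]
      if (is.na(slope)) { slope <- 0 }   # zero strength variance in train
      sTest <- networkStrength(cohort[, test, drop = FALSE], edges)
      predictions[test] <- intercept + slope * sTest
    }
    folds[[f]] <- list(train = train, test = test, selection = sel,
                       slope = unname(slope), intercept = unname(intercept))
  }
  if (emptyFolds > 0L) {
    warning(emptyFolds, " fold(s) selected no ", tail,
            "-tail edges; their predictions fall back to the training mean")
  }
  nRegions <- .nRegionsFromEdges(nrow(cohort))
  consensus <- function(whichTail) {
    sets <- lapply(folds, function(f) slot(f$selection, whichTail))
    Reduce(intersectEdges, sets)
  }
  r <- if (stats::sd(predictions) > 0) stats::cor(predictions, scores)
       else 0
  tStat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tStat), df = n - 2, lower.tail = FALSE)
  new("CpmResult", folds = folds, predictions = predictions,
      observed = as.numeric(scores), rPredObs = r, pPredObs = p,
      consensusPositive = consensus("positive"),
      consensusNegative = consensus("negative"),
      tail = tail, k = k, thresholdP = thresholdP,
      seed = as.integer(seed))
}

setMethod("show", "CpmResult", function(object) {
  cat(sprintf(
    "CPM result: %d-fold CV, %s tail, r(pred, obs) = %.3f (p = %.4g)\n",
    object@k, object@tail, object@rPredObs, object@pPredObs))
  cat("  consensus edges: positive", length(object@consensusPositive),
      "/ negative", length(object@consensusNegative), "\n")
})

#' Combine two consensus networks (e.g. into a psychomotor network)
#'
#' Set union of two edge sets with per-edge provenance ("a", "b" or
#' "both"), as used to merge the DST-positive and NCT-negative consensus
#' networks into one combined predictor network.
#'
#' @param a,b [EdgeSet-class]s over the same region universe.
#' @param tags length-2 provenance labels for edges unique to `a` / `b`.
#' @return an [EdgeSet-class] with provenance; node degrees available via
#'   [networkDegrees()].
#' @export
combineNetworks <- function(a, b, tags = c("a", "b")) {
  .sameUniverse(a, b)
  ia <- edgeIndices(a); ib <- edgeIndices(b)
  all <- sort(union(ia, ib))
  prov <- ifelse(all %in% ia & all %in% ib, "both",
                 ifelse(all %in% ia, tags[1], tags[2]))
  es <- edgeSetFromIndices(all, nRegions(a), .pickLabels(a, b))
  es@provenance <- prov[match(edgeIndices(es), all)]
  validObject(es)
  es
}

#' Per-node degree within an edge set
#' @param edges an [EdgeSet-class].
#' @return named integer vector (names = region labels when available).
#' @export
networkDegrees <- function(edges) {
  p <- edgePairs(edges)
  nodes <- edgeNodes(edges)
  deg <- tabulate(as.integer(p), nbins = nRegions(edges))[nodes]
  names(deg) <- if (length(regionLabels(edges))) {
    regionLabels(edges)[nodes]
  } else as.character(nodes)
  deg
}

#' Apply a fixed network to a cohort (post hoc brain-behavior model)
#'
#' Simple linear regression of a behavioral score on the mean strength of a
#' fixed edge set, as used to test whether a network selected in one group
#' still predicts behavior in another.
#'
#' @param cohort E x n edge matrix or [ConnectomeCohort-class] (n >= 3).
#' @param edges non-empty [EdgeSet-class].
#' @param scores length-n scores, or a phenotype column name for cohorts.
#' @return list with `r` (Pearson), `F` statistic, `df` = c(1, n - 2),
#'   two-tailed `p`, `beta` (score units per z) and `intercept`.
#' @export
applyNetwork <- function(cohort, edges, scores) {
  if (is(cohort, "ConnectomeCohort")) {
    if (is.character(scores) && length(scores) == 1L) {
      scores <- phenotype(cohort)[[scores]]
    }
    cohort <- edgeMatrix(cohort)
  }
  n <- ncol(cohort)
  if (n < 3L) stop("need at least 3 subjects")
  s <- networkStrength(cohort, edges)
  if (stats::sd(s) == 0) stop("zero strength variance over the cohort")
  fit <- stats::lm(scores ~ s)
  r <- stats::cor(s, scores)
  Fstat <- (n - 2) * r^2 / max(1 - r^2, .Machine$double.eps)
  p <- stats::pf(Fstat, 1, n - 2, lower.tail = FALSE)
  list(r = r, F = Fstat, df = c(1L, n - 2L), p = p,
       beta = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       strengths = s)
}
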