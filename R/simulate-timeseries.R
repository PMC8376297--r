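#' Shrink a correlation matrix toward identity until positive definite
#'
#' Convex shrinkage `(1 - lambda) * R + lambda * I` with the smallest
#' `lambda` achieving a minimum eigenvalue of at least `minEigen`.
#'
#' @param R symmetric correlation matrix.
#' @param minEigen eigenvalue floor (default 1e-3).
#' @return list with the shrunk matrix `C` and the `lambda` used.
#' @export
shrinkToPositiveDefinite <- function(R, minEigen = 1e-3) {
  emin <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  lambda <- if (emin >= minEigen) 0 else (minEigen - emin) / (1 - emin)
  if (lambda < 0 || lambda >= 1) {
    stop("cannot shrink to positive definiteness (min eigenvalue ",
         signif(emin, 4), ")")
  }
  C <- (1 - lambda) * R + lambda * diag(nrow(R))
  emin2 <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
  if (emin2 < minEigen * (1 - 1e-6)) {
    stop("target matrix not positive definite after shrinkage")
  }
  list(C = C, lambda = lambda)
}

#' Simulate a cohort of ROI time series (time-series mode)
#'
#' Each subject-session's T x N BOLD series is drawn from a zero-mean
#' multivariate normal whose correlation matrix is `tanh` of that
#' subject's target Fisher-z matrix (the same base + planted offsets +
#' subject strength factor used by [simulateConnectomes()], without the
#' i.i.d. edge noise — sampling noise arises from the finite series
#' length). Targets are shrunk toward identity until positive definite;
#' the shrinkage factor per subject is recorded in the truth. Empirical
#' connectivity converges to the (shrunk) target as T grows.
#'
#' @param config a [simulationConfig()]; `config@timepoints` sets T
#'   (must be >= 50).
#' @param regionLabels optional region names.
#' @return a [TimeSeriesCohort-class].
#' @export
simulateTimeseries <- function(config, regionLabels = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  T <- config@timepoints
  if (T < 50L) stop("timepoints must be >= 50 (got ", T, ")")
  N <- config@nRegions
  E <- nEdges(N)
  if (is.null(regionLabels) && N == 116L) regionLabels <- aalRegionLabels()
  set.seed(config@seed)
  baseZ <- stats::rnorm(E, config@baseMeanZ, config@baseSdZ)
  design <- .cohortDesign(config)
  series <- vector("list", nrow(design))
  lambdas <- numeric(nrow(design))
  for (row in seq_len(nrow(design))) {
    sub <- .subjectEdgeVector(config, baseZ, design, row, E)
    R <- tanh(matricizeVector(sub$target, regionLabels))
    diag(R) <- 1
    shr <- shrinkToPositiveDefinite(R)
    lambdas[row] <- shr$lambda
    set.seed(.subjectSeed(config@seed,
                          design$counter[row] * 2L +
                            (design$session[row] == "post") + 500000L))
    X <- matrix(stats::rnorm(T * N), T, N) %*% chol(shr$C)
    colnames(X) <- regionLabels
    attr(X, "samplingInterval") <- config@samplingInterval
    series[[row]] <- X
  }
  names(series) <- paste(design$subject, design$session, sep = "_")
  truth <- list(
    disruptedEdges = config@disruptedEdges, deltaZ = config@deltaZ,
    hyperEdges = config@hyperEdges, hyperDeltaZ = config@hyperDeltaZ,
    pmnEdges = config@pmnEdges, couplingBeta = config@couplingBeta,
    moderationGamma = config@moderationGamma,
    shrinkageLambda = lambdas,
    referenceGroup = design$reference[1], config = config
  )
  new("TimeSeriesCohort", series = series,
      phenotype = design[, c("subject", "group", "session")],
      samplingInterval = config@samplingInterval,
      regionLabels = as.character(regionLabels %||% character()),
      truth = truth)
}

#' Convert a time-series cohort to a connectome cohort
#'
#' Runs the Pearson/Fisher connectivity step (optionally after temporal
#' preprocessing) on every series and packs the matrices into a
#' [ConnectomeCohort-class], carrying the ground truth through.
#'
#' @param tsc a [TimeSeriesCohort-class].
#' @param preprocess apply [detrendBandpass()] first.
#' @param ... passed to [detrendBandpass()].
#' @export
cohortFromTimeSeries <- function(tsc, preprocess = FALSE, ...) {
  stopifnot(is(tsc, "TimeSeriesCohort"))
  mats <- lapply(tsc@series, function(x) {
    if (preprocess) x <- detrendBandpass(x, ...)
    connectivityMatrix(x)
  })
  ConnectomeCohort(mats, tsc@phenotype,
                   regionLabels = tsc@regionLabels, truth = tsc@truth)
}
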