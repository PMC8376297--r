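# shared fixtures built in code

# random symmetric zero-diagonal matrix
randomZMatrix <- function(n, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

# small two-group cohort with a planted group difference
smallTwoGroupCohort <- function(nRegions = 20, groupSize = 15,
                                deltaZ = 0.8, noiseSdZ = 0.1,
                                disruptedSize = 5, seed = 1) {
  cfg <- simulationConfig(
    nRegions = nRegions,
    groupSizes = c(HC = groupSize, patient = groupSize),
    postSizes = integer(), paired = FALSE,
    disruptedSize = disruptedSize, pmnSize = 4L, hyperSize = 4L,
    deltaZ = deltaZ, hyperDeltaZ = 0, noiseSdZ = noiseSdZ, seed = seed)
  list(cohort = simulateConnectomes(cfg), config = cfg)
}

# healthy cohort with behavior coupled at a target R^2
hcCohortWithBehavior <- function(n = 32, nRegions = 40, r2 = 0.5,
                                 seed = 1, couplingBeta = 12) {
  cfg <- simulationConfig(
    nRegions = nRegions, groupSizes = c(HC = n), postSizes = integer(),
    paired = FALSE, hyperDeltaZ = 0, couplingBeta = couplingBeta,
    pmnSize = 10L, disruptedSize = 6L, hyperSize = 6L, seed = seed)
  cohort <- simulateConnectomes(cfg)
  s <- networkStrength(cohort, cfg@pmnEdges)
  noiseSd <- if (is.null(r2)) 0 else behaviorNoiseForR2(s, couplingBeta, r2)
  cfg2 <- simulationConfig(
    nRegions = nRegions, groupSizes = c(HC = n), postSizes = integer(),
    paired = FALSE, hyperDeltaZ = 0, couplingBeta = couplingBeta,
    pmnSize = 10L, disruptedSize = 6L, hyperSize = 6L,
    behaviorNoiseSd = noiseSd, seed = seed)
  list(cohort = simulateBehavior(cohort, cfg2), config = cfg2)
}
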