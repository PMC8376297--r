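test_that("plantEdgeSet returns connected sets of the requested size", {
  # only one possibility: the complete graph on 5 nodes
  es <- plantEdgeSet(5, 10, rngSeed = 3)
  expect_equal(length(es), 10)
  expect_identical(edgeIndices(es), 1:10)

  # connectivity verified with the brute-force traversal oracle
  for (seed in c(1, 2, 7)) {
    es <- plantEdgeSet(116, 17, rngSeed = seed)
    expect_equal(length(es), 17)
    comps <- bruteForceComponents(edgePairs(es), 116)
    expect_length(comps, 1)
    expect_equal(comps[[1]]$size, 17)
  }
  # sparse, tree-like scale: 17 edges span 16 nodes
  expect_equal(length(edgeNodes(plantEdgeSet(116, 17, rngSeed = 1))), 16)

  expect_error(plantEdgeSet(3, 4), "exceeds the 3")
})

test_that("direct-z generator plants the group difference at the stated size", {
  cfg <- simulationConfig(
    nRegions = 40, groupSizes = c(HC = 32, patient = 36),
    postSizes = integer(), paired = FALSE,
    disruptedSize = 17, deltaZ = 0.5, hyperDeltaZ = 0,
    noiseSdZ = 0.1, seed = 11)
  cohort <- simulateConnectomes(cfg)
  ph <- phenotype(cohort)
  X <- edgeMatrix(cohort)
  dHC <- rowMeans(X[, ph$group == "HC"])
  dPat <- rowMeans(X[, ph$group == "patient"])
  diff <- dHC - dPat
  planted <- edgeIndices(cohortTruth(cohort)$disruptedEdges)
  se <- 0.1 * sqrt(1 / 32 + 1 / 36)
  expect_lt(abs(mean(diff[planted]) - 0.5), 3 * se / sqrt(17))
  offPlanted <- setdiff(seq_len(nrow(X)),
                        c(planted, edgeIndices(cfg@pmnEdges)))
  expect_lt(abs(mean(diff[offPlanted])), 3 * se / sqrt(length(offPlanted)))
})

test_that("paired pre/post difference recovers deltaZ and zero-noise cohorts are degenerate", {
  cfg <- simulationConfig(
    nRegions = 30, groupSizes = c(HC = 4, OHE = 20),
    postSizes = c(OHE = 20), paired = TRUE,
    disruptedSize = 6, deltaZ = 0.7, hyperDeltaZ = 0,
    noiseSdZ = 0.05, seed = 5)
  cohort <- simulateConnectomes(cfg)
  ph <- phenotype(cohort)
  X <- edgeMatrix(cohort)
  planted <- edgeIndices(cohortTruth(cohort)$disruptedEdges)
  pre <- X[planted, ph$group == "OHE" & ph$session == "pre"]
  post <- X[planted, ph$group == "OHE" & ph$session == "post"]
  # same subject order in both sessions
  expect_identical(ph$subject[ph$session == "pre" & ph$group == "OHE"],
                   ph$subject[ph$session == "post" & ph$group == "OHE"])
  pairedDiff <- mean(post - pre)
  se <- 0.05 * sqrt(2) / sqrt(6 * 20)
  expect_lt(abs(pairedDiff - 0.7), 3 * se)

  # deltaZ = 0, all noise off: every matrix identical up to planted behavior factor
  cfg0 <- simulationConfig(
    nRegions = 10, groupSizes = c(HC = 3, patient = 3),
    postSizes = integer(), paired = FALSE, disruptedSize = 3,
    pmnSize = 3, hyperSize = 3, deltaZ = 0, hyperDeltaZ = 0,
    noiseSdZ = 0, subjectStrengthSd = 0, seed = 2)
  X0 <- edgeMatrix(simulateConnectomes(cfg0))
  expect_equal(max(apply(X0, 1, function(r) diff(range(r)))), 0)
})

test_that("generator is bit-identical under a fixed seed and stable under cohort growth", {
  cfg <- simulationConfig(nRegions = 15, groupSizes = c(HC = 5, OHE = 4),
                          postSizes = c(OHE = 2), disruptedSize = 4,
                          pmnSize = 4, hyperSize = 4, seed = 42)
  a <- simulateBehavior(simulateConnectomes(cfg), cfg)
  b <- simulateBehavior(simulateConnectomes(cfg), cfg)
  expect_identical(edgeMatrix(a), edgeMatrix(b))
  expect_identical(phenotype(a)$DST, phenotype(b)$DST)

  # growing a group appends subjects without reshuffling existing ones
  cfgBig <- simulationConfig(nRegions = 15, groupSizes = c(HC = 5, OHE = 6),
                             postSizes = c(OHE = 2), disruptedSize = 4,
                             pmnSize = 4, hyperSize = 4, seed = 42)
  big <- simulateConnectomes(cfgBig)
  shared <- colnames(edgeMatrix(a))
  expect_identical(edgeMatrix(big)[, shared], edgeMatrix(a)[, shared])
})

test_that("behavior generator honors the coupling and moderation structure", {
  fix <- hcCohortWithBehavior(n = 24, nRegions = 30, r2 = NULL, seed = 3)
  ph <- phenotype(fix$cohort)
  s <- networkStrength(fix$cohort, fix$config@pmnEdges)
  # noiseless coupling: scores are exact affine images of strength
  expect_equal(cor(s, ph$DST), 1, tolerance = 1e-12)
  expect_equal(cor(s, ph$NCT), -1, tolerance = 1e-12)

  # zero coupling, zero noise: all scores equal the intercept
  cfg0 <- simulationConfig(nRegions = 30, groupSizes = c(HC = 6),
                           postSizes = integer(), paired = FALSE,
                           couplingBeta = 0, behaviorNoiseSd = 0,
                           moderationGamma = 0, hyperDeltaZ = 0,
                           pmnSize = 5, disruptedSize = 5, hyperSize = 5,
                           seed = 9)
  co0 <- simulateBehavior(simulateConnectomes(cfg0), cfg0)
  expect_equal(unique(round(phenotype(co0)$DST, 10)), cfg0@interceptDST)
  expect_equal(unique(round(phenotype(co0)$NCT, 10)), cfg0@interceptNCT)

  # R^2 = 0.5 noise calibration gives correlation near 1/sqrt(2)
  fix2 <- hcCohortWithBehavior(n = 400, nRegions = 30, r2 = 0.5, seed = 4)
  s2 <- networkStrength(fix2$cohort, fix2$config@pmnEdges)
  expect_equal(abs(cor(s2, phenotype(fix2$cohort)$DST)), sqrt(0.5),
               tolerance = 0.08)
  expect_error(
    simulateBehavior(fix$cohort,
                     simulationConfig(nRegions = 30,
                                      groupSizes = c(HC = 24),
                                      postSizes = integer(), paired = FALSE,
                                      pmnEdges = EdgeSet(NULL, 30),
                                      pmnSize = 5, disruptedSize = 5,
                                      hyperSize = 5, seed = 1)),
    "empty")
})

test_that("time-series mode matches the tanh-transformed target and converges with T", {
  # uniform z = 0.55 on a 3-region universe: empirical r ~ tanh(0.55) ~ 0.5005
  cfg <- simulationConfig(nRegions = 3, groupSizes = c(HC = 2),
                          postSizes = integer(), paired = FALSE,
                          baseMeanZ = 0.55, baseSdZ = 0, noiseSdZ = 0,
                          subjectStrengthSd = 0, timepoints = 10000,
                          disruptedSize = 1, pmnSize = 1, hyperSize = 1,
                          deltaZ = 0, hyperDeltaZ = 0, seed = 21)
  tsc <- simulateTimeseries(cfg)
  expect_equal(dim(tsc@series[[1]]), c(10000L, 3L))
  expect_equal(max(tsc@truth$shrinkageLambda), 0)
  co <- cohortFromTimeSeries(tsc)
  # pmn edge carries no subject factor here (sd = 0), so all edges target 0.55
  rEmp <- tanh(edgeMatrix(co))
  expect_lt(max(abs(rEmp - tanh(0.55))), 3 / sqrt(10000) + 0.01)

  # mean |empirical - target| correlation decreases monotonically in T
  err <- vapply(c(100, 1000, 10000), function(T) {
    cfgT <- simulationConfig(nRegions = 6, groupSizes = c(HC = 2),
                             postSizes = integer(), paired = FALSE,
                             timepoints = T, noiseSdZ = 0,
                             subjectStrengthSd = 0,
                             disruptedSize = 2, pmnSize = 2, hyperSize = 2,
                             deltaZ = 0, hyperDeltaZ = 0, seed = 31)
    tscT <- simulateTimeseries(cfgT)
    coT <- cohortFromTimeSeries(tscT)
    # the zero-noise direct-z cohort is exactly the target z
    direct <- edgeMatrix(simulateConnectomes(cfgT))
    mean(abs(tanh(edgeMatrix(coT)) - tanh(direct)))
  }, 0)
  expect_true(all(diff(err) < 0))
  expect_error(simulateTimeseries(
    simulationConfig(nRegions = 6, groupSizes = c(HC = 2),
                     postSizes = integer(), paired = FALSE,
                     timepoints = 40, disruptedSize = 2, pmnSize = 2,
                     hyperSize = 2, seed = 1)), ">= 50")
})
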