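test_that("edge selection splits tails by sign and is antisymmetric in the score", {
  fix <- hcCohortWithBehavior(n = 24, nRegions = 25, r2 = NULL, seed = 14)
  X <- edgeMatrix(fix$cohort)
  scores <- phenotype(fix$cohort)$DST

  # score identical to one edge's values: that edge lands in the positive tail
  y <- X[10, ]
  sel <- selectEdges(X, y, thresholdP = 0.01)
  expect_true(10L %in% edgeIndices(sel@positive))
  expect_lt(sel@p[10], 1e-20)

  # negating scores swaps the tails exactly
  selDst <- selectEdges(X, scores, thresholdP = 0.01)
  selNeg <- selectEdges(X, -scores, thresholdP = 0.01)
  expect_identical(edgeIndices(selDst@positive),
                   edgeIndices(selNeg@negative))
  expect_identical(edgeIndices(selDst@negative),
                   edgeIndices(selNeg@positive))

  # constant edge is skipped with a message
  X2 <- X; X2[1, ] <- 5
  expect_message(sel2 <- selectEdges(X2, scores), "constant")
  expect_false(1L %in% c(edgeIndices(sel2@positive),
                         edgeIndices(sel2@negative)))
  expect_error(selectEdges(X, rep(1, ncol(X))), "zero variance")
})

test_that("null edge selection fires at roughly the nominal rate", {
  set.seed(90)
  E <- nEdges(50); n <- 30
  X <- matrix(rnorm(E * n), E, n)
  scores <- rnorm(n)
  sel <- selectEdges(X, scores, thresholdP = 0.01)
  nSel <- length(sel@positive) + length(sel@negative)
  # expected E * 0.01 ~ 12.25 selections; allow generous Poisson-scale slack
  expect_lt(abs(nSel - E * 0.01), 4 * sqrt(E * 0.01))
})

test_that("network strength is the mean z over the edge set and is linear", {
  m <- matrix(0, 4, 4)
  m[1, 2] <- m[2, 1] <- 0.2
  m[1, 3] <- m[3, 1] <- 0.4
  m[2, 3] <- m[3, 2] <- 0.6
  es3 <- EdgeSet(rbind(c(1, 2), c(1, 3), c(2, 3)), 4)
  es1 <- EdgeSet(rbind(c(1, 3)), 4)
  expect_equal(networkStrength(m, es3), 0.4)
  expect_equal(networkStrength(m, es1), 0.4)
  expect_equal(networkStrength(3 * m, es3), 3 * networkStrength(m, es3))
  expect_error(networkStrength(m, EdgeSet(NULL, 4)), "empty")
  # edge-matrix form gives one strength per subject
  X <- cbind(vectorizeMatrix(m), vectorizeMatrix(2 * m))
  expect_equal(unname(networkStrength(X, es3)), c(0.4, 0.8))
})

test_that("cross-validated CPM recovers a noiseless linear coupling", {
  fix <- hcCohortWithBehavior(n = 32, nRegions = 40, r2 = NULL, seed = 15)
  res <- cpmCrossval(fix$cohort, "DST", k = 5, seed = 3)
  expect_gte(res@rPredObs, 0.99)
  # consensus edges are contained in every fold's selection
  for (f in res@folds) {
    expect_true(all(edgeIndices(res@consensusPositive) %in%
                    edgeIndices(f$selection@positive)))
  }
  expect_lte(length(res@consensusPositive),
             min(vapply(res@folds,
                        function(f) length(f$selection@positive), 0)))
  # the planted behavior edges dominate the consensus
  planted <- edgeIndices(cohortTruth(fix$cohort)$pmnEdges)
  expect_gt(length(intersect(edgeIndices(res@consensusPositive), planted)),
            0.5 * length(planted))
  # NCT couples negatively: the negative tail predicts it
  resN <- cpmCrossval(fix$cohort, "NCT", k = 5, tail = "negative", seed = 3)
  expect_gte(resN@rPredObs, 0.99)
  expect_gt(length(intersect(edgeIndices(resN@consensusNegative), planted)),
            0.5 * length(planted))
})

test_that("every subject is predicted exactly once, incl. leave-one-out", {
  fix <- hcCohortWithBehavior(n = 14, nRegions = 20, r2 = 0.5, seed = 16)
  X <- edgeMatrix(fix$cohort)
  scores <- phenotype(fix$cohort)$DST
  res5 <- suppressWarnings(cpmCrossval(X, scores, k = 5, seed = 4))
  tested <- sort(unlist(lapply(res5@folds, `[[`, "test")))
  expect_identical(tested, 1:14)
  loo <- suppressWarnings(cpmCrossval(X, scores, k = 14, seed = 4))
  expect_identical(vapply(loo@folds, function(f) length(f$test), 0L),
                   rep(1L, 14))
  expect_error(cpmCrossval(X, scores, k = 15, seed = 1), "exceed")
})

test_that("prediction correlation is invariant to affine rescaling of the connectomes", {
  fix <- hcCohortWithBehavior(n = 24, nRegions = 25, r2 = 0.5, seed = 17)
  X <- edgeMatrix(fix$cohort)
  scores <- phenotype(fix$cohort)$DST
  a <- suppressWarnings(cpmCrossval(X, scores, k = 4, seed = 6))
  b <- suppressWarnings(cpmCrossval(3.7 * X, scores, k = 4, seed = 6))
  expect_equal(a@rPredObs, b@rPredObs, tolerance = 1e-10)
  expect_equal(a@predictions, b@predictions, tolerance = 1e-8)
})

test_that("combineNetworks takes the union with provenance and degrees", {
  a <- EdgeSet(cbind(1:6, 2:7), 30)               # 6 edges
  b <- EdgeSet(cbind(11:22, 12:23), 30)           # 12 edges, disjoint
  pmn <- combineNetworks(a, b, tags = c("positive", "negative"))
  expect_equal(length(pmn), 18)
  expect_setequal(unique(edgeProvenance(pmn)), c("positive", "negative"))
  expect_equal(sum(edgeProvenance(pmn) == "positive"), 6)
  # identity and idempotence
  expect_equal(length(combineNetworks(a, a)), length(a))
  expect_true(all(edgeProvenance(combineNetworks(a, a)) == "both"))
  expect_identical(edgeIndices(combineNetworks(EdgeSet(NULL, 30), b)),
                   edgeIndices(b))
  deg <- networkDegrees(pmn)
  expect_equal(sum(deg), 2 * 18)
})

test_that("applyNetwork returns the exact fit and the F = (n-2)r^2/(1-r^2) identity", {
  fix <- hcCohortWithBehavior(n = 23, nRegions = 25, r2 = 0.5, seed = 18)
  X <- edgeMatrix(fix$cohort)
  edges <- fix$config@pmnEdges
  s <- networkStrength(X, edges)
  # exact linear scores: r = 1, beta = 2
  fitExact <- applyNetwork(X, edges, 2 * s + 5)
  expect_equal(fitExact$r, 1, tolerance = 1e-10)
  expect_equal(fitExact$beta, 2, tolerance = 1e-10)
  # identity holds on noisy scores too
  fit <- applyNetwork(X, edges, phenotype(fix$cohort)$DST)
  expect_equal(fit$F, (23 - 2) * fit$r^2 / (1 - fit$r^2), tolerance = 1e-10)
  expect_equal(fit$df, c(1L, 21L))
  expect_error(applyNetwork(X[, 1:2], edges, 1:2), "at least 3")
})
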