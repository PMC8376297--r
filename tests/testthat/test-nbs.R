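test_that("edge-wise t matches the hand-computed pooled statistic", {
  # groups {1,2,3} vs {4,5,6}: pooled t = -3.674, df = 4
  A <- matrix(rep(c(1, 2, 3), each = 3), nrow = 3)  # 3 edges x 3 subjects
  B <- matrix(rep(c(4, 5, 6), each = 3), nrow = 3)
  tm <- edgewiseT(A, B, tail = "less")
  expect_equal(unname(tm@df), 4)
  expect_equal(tm@t, rep(3.6742346, 3), tolerance = 1e-6)
  expect_equal(tm@p, rep(pt(3.6742346, 4, lower.tail = FALSE), 3),
               tolerance = 1e-6)
  # the disfavored tail puts the same magnitude on the other side
  tmG <- edgewiseT(A, B, tail = "greater")
  expect_equal(tmG@p, 1 - tm@p, tolerance = 1e-6)
})

test_that("identical groups give t = 0 and one-tailed p = 0.5; swap is antisymmetric", {
  set.seed(4)
  X <- matrix(rnorm(6 * 5), 6, 5)
  same <- suppressMessages(edgewiseT(X, X, tail = "greater"))
  expect_equal(same@t, rep(0, 6))
  expect_equal(same@p, rep(0.5, 6))

  A <- matrix(rnorm(10 * 7), 10, 7)
  B <- matrix(rnorm(10 * 9), 10, 9)
  ab <- edgewiseT(A, B, tail = "greater")
  ba <- edgewiseT(B, A, tail = "less")
  expect_equal(ab@p, ba@p, tolerance = 1e-12)
  expect_equal(ab@t, ba@t, tolerance = 1e-12)
})

test_that("edge inclusion mask keeps strongly nonzero edges and drops null ones", {
  set.seed(12)
  E <- nEdges(116)
  n <- 30
  strong <- matrix(rnorm(n, 1.0, 0.1), nrow = 1)
  zero <- matrix(0, nrow = 1, ncol = n)
  nullish <- matrix(rnorm((E - 2) * n), E - 2, n)
  X <- rbind(strong, zero, nullish)
  mask <- edgeInclusionMask(list(X), alpha = 0.05)
  expect_true(mask[1])
  expect_false(mask[2])
  # null edges pass the Bonferroni screen at roughly rate alpha in total
  expect_lt(sum(mask[-(1:2)]), 5)
  expect_error(edgeInclusionMask(list(X[, 1, drop = FALSE])), ">= 2")
})

test_that("suprathreshold components match hand-worked cases and the DFS oracle", {
  # edges (1,2),(2,3),(5,6) -> components of sizes 2 and 1
  p <- rep(NA_real_, nEdges(6))
  p[c(edgeIndex(1, 2, 6), edgeIndex(2, 3, 6), edgeIndex(5, 6, 6))] <- 1e-6
  comps <- suprathresholdComponents(p, 1e-4, nRegions = 6)
  expect_equal(vapply(comps, `[[`, 0, "size"), c(2, 1))
  expect_equal(comps[[1]]$nodes, 1:3)

  # triangle: one component, 3 edges, 3 nodes
  p2 <- rep(NA_real_, nEdges(5))
  p2[c(edgeIndex(1, 2, 5), edgeIndex(2, 3, 5), edgeIndex(1, 3, 5))] <- 1e-6
  comps2 <- suprathresholdComponents(p2, 1e-4, nRegions = 5)
  expect_length(comps2, 1)
  expect_equal(comps2[[1]]$size, 3)
  expect_equal(comps2[[1]]$nodes, 1:3)

  # empty graph
  expect_length(suprathresholdComponents(rep(0.9, 10), 1e-4, nRegions = 5), 0)

  # equivalence with the brute-force DFS oracle on random graphs
  set.seed(77)
  for (g in 1:200) {
    n <- sample(3:12, 1)
    map <- edgeIndexMap(n)
    keep <- runif(nrow(map)) < runif(1, 0.05, 0.5)
    pv <- ifelse(keep, 1e-9, 0.99)
    a <- suprathresholdComponents(pv, 1e-4, nRegions = n)
    b <- bruteForceComponents(map[keep, , drop = FALSE], n)
    expect_equal(lapply(a, function(co) sort(edgeIndices(co$edges))),
                 lapply(b, function(co) sort(edgeIndices(co$edges))))
  }
})

test_that("nbsTest recovers a planted component with the counting-definition p", {
  fix <- smallTwoGroupCohort(nRegions = 20, groupSize = 15, deltaZ = 1.0,
                             noiseSdZ = 0.1, disruptedSize = 5, seed = 31)
  ph <- phenotype(fix$cohort)
  X <- edgeMatrix(fix$cohort)
  expect_warning(
    res <- nbsTest(X[, ph$group == "HC"], X[, ph$group == "patient"],
                   tail = "greater", primaryP = 1e-3, nPerm = 99, seed = 2),
    "coarse")
  expect_s4_class(res, "NbsResult")
  planted <- sort(edgeIndices(cohortTruth(fix$cohort)$disruptedEdges))
  expect_identical(sort(edgeIndices(res@components[[1]]$edges)), planted)
  # observed max exceeded every permutation max -> p = 1/(nPerm + 1)
  expect_true(all(res@nullMaxSizes < res@components[[1]]$size))
  expect_equal(res@correctedP[1], 1 / 100)
  # literal strict-proportion estimator (clamped off 0)
  resLit <- suppressWarnings(
    nbsTest(X[, ph$group == "HC"], X[, ph$group == "patient"],
            tail = "greater", primaryP = 1e-3, nPerm = 99, seed = 2,
            paperLiteral = TRUE))
  expect_lt(resLit@correctedP[1], 1 / 100)
})

test_that("corrected p is monotone in component size and seeds reproduce", {
  # plant two disjoint connected sets of different sizes
  big <- EdgeSet(cbind(1:8, 2:9), 30)     # 8-edge chain on nodes 1..9
  small <- EdgeSet(rbind(c(25, 26), c(26, 27), c(27, 28)), 30)
  cfg <- simulationConfig(nRegions = 30, groupSizes = c(HC = 15, P = 15),
                          postSizes = integer(), paired = FALSE,
                          disruptedEdges = big, deltaZ = 1.2,
                          hyperDeltaZ = 0, pmnSize = 3, hyperSize = 3,
                          noiseSdZ = 0.35, seed = 8)
  co <- simulateConnectomes(cfg)
  X <- edgeMatrix(co)
  ph <- phenotype(co)
  # lower the small set only in patients by editing the matrix directly
  idx <- edgeIndices(small)
  X[idx, ph$group == "P"] <- X[idx, ph$group == "P"] - 1.0
  r1 <- nbsTest(X[, ph$group == "HC"], X[, ph$group == "P"],
                tail = "greater", primaryP = 1e-3, nPerm = 200, seed = 5)
  sizes <- vapply(r1@components, `[[`, 0, "size")
  expect_true(all(diff(sizes) <= 0))
  expect_true(all(diff(r1@correctedP) >= 0))
  r2 <- nbsTest(X[, ph$group == "HC"], X[, ph$group == "P"],
                tail = "greater", primaryP = 1e-3, nPerm = 200, seed = 5)
  expect_identical(r1@nullMaxSizes, r2@nullMaxSizes)
  expect_identical(r1@correctedP, r2@correctedP)
})

test_that("null nbs on exchangeable groups stays quiet and paired mode runs", {
  fix <- smallTwoGroupCohort(nRegions = 15, groupSize = 12, deltaZ = 0,
                             noiseSdZ = 0.1, seed = 13)
  ph <- phenotype(fix$cohort)
  X <- edgeMatrix(fix$cohort)
  res <- nbsTest(X[, ph$group == "HC"], X[, ph$group == "patient"],
                 tail = "greater", primaryP = 1e-2, nPerm = 200, seed = 3)
  expect_true(length(res@correctedP) == 0 || min(res@correctedP) > 0.05)

  resP <- nbsTest(X[, ph$group == "HC"], X[, ph$group == "patient"],
                  tail = "greater", primaryP = 1e-2, nPerm = 100,
                  seed = 3, paired = TRUE)
  expect_s4_class(resP, "NbsResult")
  expect_length(resP@nullMaxSizes, 100)
  expect_error(nbsTest(X[, 1:3], X[, 4:8], paired = TRUE), "equal group")
  expect_warning(nbsTest(X[, 1:5], X[, 6:10], nPerm = 50, seed = 1),
                 "coarse")
})
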