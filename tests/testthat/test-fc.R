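test_that("detrend removes constants and trends; band-pass has the stated frequency response", {
  T <- 400; dt <- 2.5; tt <- (0:(T - 1)) * dt
  const <- roiTimeSeries(cbind(rep(3, T), 5 + 0.01 * tt), dt)
  out <- detrendBandpass(const)
  expect_lt(max(abs(out)), 1e-8)

  core <- 50:350   # avoid edge transients when measuring amplitude
  gainAt <- function(f) {
    x <- roiTimeSeries(cbind(sin(2 * pi * f * tt),
                             cos(2 * pi * f * tt)), dt)
    y <- detrendBandpass(x)
    sd(y[core, 1]) / sd(x[core, 1])
  }
  expect_gt(gainAt(0.05), 0.9)    # in band
  expect_lt(gainAt(0.19), 0.1)    # above band
  expect_lt(gainAt(0.002), 0.1)   # below band (slow drift)
})

test_that("band-pass filter is zero-phase (time-reversal symmetric)", {
  set.seed(8)
  x <- roiTimeSeries(matrix(rnorm(400 * 3), 400, 3), 2.5)
  a <- detrendBandpass(x)
  b <- detrendBandpass(roiTimeSeries(x[400:1, ], 2.5))[400:1, ]
  expect_lt(max(abs(a - b)), 1e-8)
})

test_that("filter input validation names the bounds", {
  x <- roiTimeSeries(matrix(rnorm(100 * 2), 100, 2), 2.5)
  expect_error(detrendBandpass(x, highHz = 0.25), "Nyquist")
  short <- roiTimeSeries(matrix(rnorm(10 * 2), 10, 2), 2.5)
  expect_error(detrendBandpass(short), "at least 27 timepoints")
})

test_that("nuisance regression performs the exact least-squares projection", {
  T <- 120
  set.seed(3)
  c1 <- sin(2 * pi * (1:T) / 20)
  s <- cos(2 * pi * (1:T) / 20)       # orthogonal to c1 over full periods
  s <- s - mean(s)
  c1 <- c1 - mean(c1)
  # signal = s + 2 * c: residual recovers s exactly
  ts <- roiTimeSeries(cbind(s + 2 * c1, rnorm(T)), 2.5)
  res <- regressNuisance(ts, cbind(c1), addDerivatives = FALSE)
  expect_lt(max(abs(res[, 1] - s)), 1e-8)

  # confound identical to the signal column: residual ~ 0
  res2 <- regressNuisance(roiTimeSeries(cbind(c1, s), 2.5), cbind(c1),
                          addDerivatives = FALSE)
  expect_lt(max(abs(res2[, 1])), 1e-10)

  # residuals orthogonal to the full design including derivatives
  conf <- matrix(rnorm(T * 3), T, 3)
  res3 <- regressNuisance(ts, conf)
  X <- cbind(1, conf, rbind(0, diff(conf)))
  expect_lt(max(abs(crossprod(X, res3))), 1e-8)

  # rank-deficient design drops columns with a warning
  expect_warning(regressNuisance(ts, cbind(c1, c1 * 2)), "rank deficient")
  expect_error(regressNuisance(ts, matrix(1, 10, 1)), "row per timepoint")
})

test_that("connectivity matrix applies the Fisher transform with clipping", {
  set.seed(5)
  a <- rnorm(200)
  b <- rnorm(200)
  ts <- cbind(a, a, b)
  expect_message(z <- connectivityMatrix(ts), "clipped")
  expect_equal(z[1, 2], atanh(1 - 1e-10))
  expect_equal(unname(diag(z)), rep(0, 3))
  expect_lt(max(abs(z - t(z))), 1e-12)

  # r = 0.5 between two columns -> z = atanh(0.5) = 0.5493
  x <- rnorm(5000)
  y <- 0.5 * x + sqrt(1 - 0.25) * rnorm(5000)
  # construct exact sample correlation 0.5 by orthogonalization
  e <- residuals(lm(y ~ x)); e <- e / sd(e)
  xs <- (x - mean(x)) / sd(x)
  yExact <- 0.5 * xs + sqrt(0.75) * e
  zz <- connectivityMatrix(cbind(xs, yExact, rnorm(5000)))
  expect_equal(zz[1, 2], atanh(0.5), tolerance = 1e-10)
  expect_equal(atanh(0.5), 0.5493061, tolerance = 1e-6)

  expect_error(connectivityMatrix(cbind(rep(1, 50), rnorm(50))),
               "zero-variance")

  # Pearson step invariant to per-column affine rescaling
  ts2 <- matrix(rnorm(100 * 4), 100, 4)
  scaled <- sweep(sweep(ts2, 2, c(2, -3, 0.5, 10), "*"),
                  2, c(1, -5, 2, 0), "+")
  z1 <- connectivityMatrix(ts2)
  z2 <- connectivityMatrix(scaled)
  off <- row(z1) != col(z1)
  expect_equal(abs(z2[off]), abs(z1[off]), tolerance = 1e-10)

  # 116-region input gives the full-size zero-diagonal matrix
  big <- connectivityMatrix(matrix(rnorm(150 * 116), 150, 116))
  expect_equal(dim(big), c(116L, 116L))
  expect_identical(diag(big), rep(0, 116))
})

test_that("cohort io round-trips matrices, phenotype and truth", {
  fix <- smallTwoGroupCohort(nRegions = 8, groupSize = 3, seed = 6,
                             disruptedSize = 3)
  cohort <- fix$cohort
  dir <- withr::local_tempdir()
  writeCohort(cohort, dir)
  back <- readCohort(dir)
  expect_equal(edgeMatrix(back), edgeMatrix(cohort), tolerance = 1e-12)
  expect_identical(phenotype(back)$subject, phenotype(cohort)$subject)
  expect_identical(edgeIndices(cohortTruth(back)$disruptedEdges),
                   edgeIndices(cohortTruth(cohort)$disruptedEdges))
  # edge vector writer produces labeled two-column TSV
  v <- vectorizeMatrix(subjectMatrix(cohort, 1))
  f <- file.path(dir, "edges.tsv")
  writeEdgeVector(v, f)
  tab <- read.delim(f)
  expect_equal(nrow(tab), nEdges(8))
  expect_equal(tab$z, unname(v), tolerance = 1e-12)
})

test_that("readers sniff delimiters and reject malformed matrices", {
  dir <- withr::local_tempdir()
  m <- randomZMatrix(4, 9)
  fcsv <- file.path(dir, "m.csv")
  write.table(m, fcsv, sep = ",", row.names = FALSE, col.names = FALSE)
  expect_equal(readConnectivityMatrix(fcsv), m, tolerance = 1e-12,
               ignore_attr = TRUE)
  bad <- file.path(dir, "bad.tsv")
  write.table(m[, 1:3], bad, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  expect_error(readConnectivityMatrix(bad), "not square")
  asym <- m; asym[1, 2] <- asym[1, 2] + 1
  fa <- file.path(dir, "asym.tsv")
  write.table(asym, fa, sep = "\t", row.names = FALSE, col.names = FALSE)
  expect_error(readConnectivityMatrix(fa), "not symmetric")
})
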