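#' Edge-inclusion mask from per-group one-sample tests
#'
#' An edge enters the mass-univariate analysis if its Fisher-z values are
#' significantly nonzero (two-tailed one-sample t test, Bonferroni-corrected
#' over all E edges at level `alpha`) in at least one group. The mask is
#' computed once on the observed data and reused across permutations.
#'
#' @param groups list of E x n edge matrices (one per group, n >= 2 each).
#' @param alpha familywise level before the Bonferroni division by E.
#' @return logical length-E inclusion mask.
#' @export
edgeInclusionMask <- function(groups, alpha = 0.05) {
  if (!length(groups)) stop("no groups supplied")
  E <- nrow(groups[[1]])
  threshold <- alpha / E
  included <- rep(FALSE, E)
  for (X in groups) {
    n <- ncol(X)
    if (n < 2L) stop("every group needs >= 2 subjects for the inclusion test")
    m <- rowMeans(X)
    s <- sqrt((rowSums(X^2) - n * m^2) / (n - 1L))
    t <- ifelse(s > 0, m / (s / sqrt(n)), ifelse(m == 0, 0, Inf))
    p <- 2 * stats::pt(abs(t), df = n - 1L, lower.tail = FALSE)
    included <- included | (p < threshold)
  }
  included
}

# vectorized two-sample t over edge rows; g is logical (TRUE = group A)
.edgeT <- function(X, X2, g, nA, nB, variance = "pooled") {
  sA <- drop(X %*% g);  sB <- drop(X %*% (!g))
  qA <- drop(X2 %*% g); qB <- drop(X2 %*% (!g))
  mA <- sA / nA; mB <- sB / nB
  vA <- pmax((qA - nA * mA^2) / (nA - 1L), 0)   # clamp fp round-off
  vB <- pmax((qB - nB * mB^2) / (nB - 1L), 0)
  if (variance == "pooled") {
    sp2 <- ((nA - 1L) * vA + (nB - 1L) * vB) / (nA + nB - 2L)
    se <- sqrt(sp2 * (1 / nA + 1 / nB))
    df <- rep.int(nA + nB - 2L, length(se))
  } else {
    se <- sqrt(vA / nA + vB / nB)
    df <- (vA / nA + vB / nB)^2 /
      ((vA / nA)^2 / (nA - 1L) + (vB / nB)^2 / (nB - 1L))
  }
  list(diff = mA - mB, se = se, df = df)
}

#' Edge-wise two-sample t tests
#'
#' Two-sample one-tailed t tests (pooled-variance Student by default,
#' optionally Welch) at every included edge.
#'
#' @param groupA,groupB E x n edge matrices (Fisher-z), n >= 2 each.
#' @param tail "greater" tests A > B, "less" tests A < B.
#' @param mask logical length-E inclusion mask (default: all included).
#' @param variance "pooled" or "welch".
#' @param nRegions region count (inferred from E when NULL).
#' @return an [EdgeTestMap-class]. Edges with zero pooled variance get
#'   p = 0.5 when the means are equal, else 0/1 by the sign of the
#'   difference relative to the tail.
#' @export
edgewiseT <- function(groupA, groupB, tail = c("greater", "less"),
                      mask = NULL, variance = c("pooled", "welch"),
                      nRegions = NULL) {
  tail <- match.arg(tail)
  variance <- match.arg(variance)
  nA <- ncol(groupA); nB <- ncol(groupB)
  if (nA < 2L || nB < 2L) stop("both groups need >= 2 subjects")
  E <- nrow(groupA)
  if (nrow(groupB) != E) stop("groups have different edge counts")
  if (is.null(nRegions)) nRegions <- .nRegionsFromEdges(E)
  if (is.null(mask)) mask <- rep(TRUE, E)
  X <- cbind(groupA, groupB)
  g <- c(rep(TRUE, nA), rep(FALSE, nB))
  et <- .edgeT(X, X^2, g, nA, nB, variance)
  sgn <- if (tail == "greater") 1 else -1
  tt <- sgn * et$diff / et$se
  p <- stats::pt(tt, df = et$df, lower.tail = FALSE)
  degenerate <- !is.na(et$se) & et$se == 0
  if (any(degenerate & mask)) {
    message(sum(degenerate & mask), " edge(s) with zero variance in both ",
            "groups; p set by the sign of the mean difference")
    tt[degenerate] <- sgn * sign(et$diff[degenerate]) * Inf
    tt[degenerate & et$diff == 0] <- 0
    p[degenerate] <- ifelse(et$diff[degenerate] == 0, 0.5,
                            ifelse(sgn * et$diff[degenerate] > 0, 0, 1))
  }
  tt[!mask] <- NA_real_
  p[!mask] <- NA_real_
  new("EdgeTestMap", t = tt, p = p, tail = tail,
      df = if (variance == "pooled") et$df[1] else et$df,
      included = mask, nRegions = as.integer(nRegions))
}

#' Connected components of the suprathreshold graph
#'
#' Builds the graph of included edges with `p < primaryP` and returns its
#' connected components (those with at least one edge), each with its edge
#' set, node list, and size measured in edges, sorted by size descending.
#'
#' @param tests an [EdgeTestMap-class] (or a numeric vector of p values).
#' @param primaryP primary edge-level threshold.
#' @param nRegions region count (taken from `tests` when it is an
#'   EdgeTestMap).
#' @param regionLabels optional labels attached to component edge sets.
#' @return list of components: each a list(edges = EdgeSet, nodes, size).
#' @export
suprathresholdComponents <- function(tests, primaryP,
                                     nRegions = NULL,
                                     regionLabels = character()) {
  if (is(tests, "EdgeTestMap")) {
    p <- tests@p
    nRegions <- tests@nRegions
  } else {
    p <- tests
    if (is.null(nRegions)) nRegions <- .nRegionsFromEdges(length(p))
  }
  idx <- which(!is.na(p) & p < primaryP)
  map <- edgeIndexMap(nRegions)
  .componentsFromEdges(map[idx, , drop = FALSE], nRegions, regionLabels)
}

.componentsFromEdges <- function(pairs, nRegions, regionLabels = character()) {
  if (!nrow(pairs)) return(list())
  nodes <- sort(unique(as.integer(pairs)))
  gr <- igraph::graph_from_edgelist(
    matrix(match(as.integer(pairs), nodes), ncol = 2L), directed = FALSE)
  memb <- igraph::components(gr)$membership
  edgeComp <- memb[match(pairs[, 1], nodes)]
  comps <- lapply(split(seq_len(nrow(pairs)), edgeComp), function(rows) {
    es <- EdgeSet(pairs[rows, , drop = FALSE], nRegions, regionLabels)
    list(edges = es, nodes = edgeNodes(es), size = length(rows))
  })
  comps <- unname(comps)
  comps[order(vapply(comps, `[[`, 0, "size"), decreasing = TRUE)]
}

# max component size (edges) of the graph with the given suprathreshold rows
.maxComponentSize <- function(pairs) {
  if (!nrow(pairs)) return(0L)
  nodes <- unique(as.integer(pairs))
  gr <- igraph::graph_from_edgelist(
    matrix(match(as.integer(pairs), nodes), ncol = 2L), directed = FALSE)
  memb <- igraph::components(gr)$membership
  max(tabulate(memb[match(pairs[, 1], nodes)]))
}

#' Network-based statistic
#'
#' Familywise-corrected test for connected components of group-difference
#' edges: mass-univariate one-tailed t tests at every included edge, a
#' primary p-value threshold defining the suprathreshold graph, and a
#' permutation null of the maximal connected component size obtained by
#' reallocating subjects to groups. Each observed component of size M
#' (edges) receives corrected p = (1 + #{permutation max >= M}) /
#' (nPerm + 1); `paperLiteral = TRUE` switches to the strict-inequality
#' proportion #{max > M} / nPerm (which can return 0).
#'
#' @param groupA,groupB E x n edge matrices, or [ConnectomeCohort-class]s
#'   (their full edge matrices are used).
#' @param tail "greater" (A > B) or "less".
#' @param primaryP primary edge-level threshold (default 1e-4).
#' @param nPerm permutation count (default 10000).
#' @param seed RNG seed for the permutations.
#' @param alphaMask level of the edge-inclusion mask ([edgeInclusionMask()]
#'   at `alphaMask`, Bonferroni over E); `NULL` disables masking.
#' @param variance "pooled" (default) or "welch".
#' @param paired treat columns as paired (both matrices n columns, column
#'   k of each from the same subject); permutations then flip each pair
#'   with probability 1/2 instead of freely reallocating subjects.
#' @param paperLiteral use the strict-> / nPerm corrected-p estimator.
#' @param regionLabels labels attached to component edge sets.
#' @return an [NbsResult-class].
#' @export
nbsTest <- function(groupA, groupB, tail = c("greater", "less"),
                    primaryP = 1e-4, nPerm = 10000L, seed = 1L,
                    alphaMask = 0.05, variance = c("pooled", "welch"),
                    paired = FALSE, paperLiteral = FALSE,
                    regionLabels = NULL) {
  tail <- match.arg(tail)
  variance <- match.arg(variance)
  if (is(groupA, "ConnectomeCohort")) {
    if (is.null(regionLabels)) regionLabels <- regionLabels(groupA)
    groupA <- edgeMatrix(groupA)
  }
  if (is(groupB, "ConnectomeCohort")) groupB <- edgeMatrix(groupB)
  nA <- ncol(groupA); nB <- ncol(groupB)
  if (nA < 2L || nB < 2L) stop("both groups need >= 2 subjects")
  if (paired && nA != nB) stop("paired mode requires equal group sizes")
  nPerm <- .checkCount(nPerm, "nPerm", min = 1L)
  if (nPerm < 100L) warning("nPerm < 100 gives coarse p-value resolution")
  E <- nrow(groupA)
  nRegions <- .nRegionsFromEdges(E)
  mask <- if (is.null(alphaMask)) rep(TRUE, E) else
    edgeInclusionMask(list(groupA, groupB), alpha = alphaMask)

  obs <- edgewiseT(groupA, groupB, tail, mask, variance, nRegions)
  comps <- suprathresholdComponents(obs, primaryP,
                                    regionLabels = regionLabels %||%
                                      character())

  X <- cbind(groupA, groupB)
  X2 <- X^2
  n <- nA + nB
  map <- edgeIndexMap(nRegions)
  maskIdx <- which(mask)
  sgn <- if (tail == "greater") 1 else -1
  set.seed(.checkCount(seed, "seed"))
  nullMax <- integer(nPerm)
  for (k in seq_len(nPerm)) {
    if (paired) {
      flip <- stats::runif(nA) < 0.5
      g <- c(!flip, flip)
    } else {
      g <- logical(n)
      g[sample.int(n, nA)] <- TRUE
    }
    et <- .edgeT(X[maskIdx, , drop = FALSE], X2[maskIdx, , drop = FALSE],
                 g, nA, nB, variance)
    tt <- sgn * et$diff / et$se
    supra <- (et$se > 0 &
                stats::pt(tt, df = et$df, lower.tail = FALSE) < primaryP) |
      (et$se == 0 & sgn * et$diff > 0)
    nullMax[k] <- .maxComponentSize(
      map[maskIdx[which(supra)], , drop = FALSE])
  }
  sizes <- vapply(comps, `[[`, 0, "size")
  correctedP <- if (paperLiteral) {
    vapply(sizes, function(M) sum(nullMax > M) / nPerm, 0)
  } else {
    vapply(sizes, function(M) (1 + sum(nullMax >= M)) / (nPerm + 1), 0)
  }
  if (paperLiteral && any(correctedP == 0)) {
    correctedP[correctedP == 0] <- .Machine$double.xmin
    warning("strict-proportion estimator returned 0; clamped to the smallest ",
            "positive double (use the default estimator for valid p values)")
  }
  new("NbsResult", components = comps, correctedP = correctedP,
      nullMaxSizes = as.numeric(nullMax), tests = obs,
      primaryP = primaryP, nPerm = nPerm, seed = as.integer(seed),
      tail = tail)
}

setMethod("show", "NbsResult", function(object) {
  cat("NBS result (tail:", object@tail, ", primary p <",
      format(object@primaryP), ",", object@nPerm, "permutations)\n")
  if (!length(object@components)) {
    cat("  no suprathreshold components\n")
    return(invisible(NULL))
  }
  for (k in seq_along(object@components)) {
    co <- object@components[[k]]
    cat(sprintf("  component %d: %d edges, %d nodes, corrected p = %.4g\n",
                k, co$size, length(co$nodes), object@correctedP[k]))
  }
})

#' Components and corrected p values as a data.frame
#' @param result an [NbsResult-class].
#' @export
nbsSummary <- function(result) {
  if (!length(result@components)) {
    return(data.frame(component = integer(), edges = integer(),
                      nodes = integer(), correctedP = numeric()))
  }
  data.frame(
    component = seq_along(result@components),
    edges = vapply(result@components, `[[`, 0, "size"),
    nodes = vapply(result@components, function(co) length(co$nodes), 0),
    correctedP = result@correctedP
  )
}
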