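#' Canonical upper-triangle edge indexing
#'
#' An N-region connectome has `E = N(N-1)/2` unordered region pairs. All
#' edge vectors in this package use one canonical ordering of those pairs:
#' row-major over the strict upper triangle, i.e. (1,2), (1,3), ..., (1,N),
#' (2,3), ..., (N-1,N).
#'
#' @param nRegions number of regions N (>= 2).
#' @return `edgeIndexMap()`: an integer matrix with E rows and columns
#'   `i`, `j` (1-based region indices, `i < j`), row k giving the region
#'   pair of edge k.
#' @examples
#' edgeIndexMap(4)
#' edgeIndex(1, 3, 4)
#' @export
edgeIndexMap <- function(nRegions) {
  nRegions <- .checkCount(nRegions, "nRegions", min = 2L)
  i <- rep.int(seq_len(nRegions - 1L), times = (nRegions - 1L):1L)
  j <- sequence((nRegions - 1L):1L, from = 2L:nRegions)
  cbind(i = i, j = j)
}

#' @rdname edgeIndexMap
#' @param i,j region indices (1-based); vectors are recycled. Order of i and
#'   j does not matter but `i != j` is required.
#' @return `edgeIndex()`: the integer edge index (1..E) of pair (i, j).
#' @export
edgeIndex <- function(i, j, nRegions) {
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  if (any(lo == hi)) stop("diagonal pairs (i == j) have no edge index")
  if (any(lo < 1L) || any(hi > nRegions)) {
    stop("region indices must lie in 1..", nRegions)
  }
  as.integer((lo - 1L) * nRegions - lo * (lo + 1L) / 2 + hi)
}

#' Number of edges of an N-region connectome
#' @inheritParams edgeIndexMap
#' @return integer, N(N-1)/2.
#' @export
nEdges <- function(nRegions) {
  as.integer(nRegions * (nRegions - 1L) / 2L)
}

# inverse triangular number; error if len is not one
.nRegionsFromEdges <- function(len) {
  n <- (1 + sqrt(1 + 8 * len)) / 2
  if (abs(n - round(n)) > 1e-9) {
    stop("vector length ", len, " is not a triangular number N(N-1)/2")
  }
  as.integer(round(n))
}

#' Convert between symmetric matrices and edge vectors
#'
#' `vectorizeMatrix()` extracts the strict upper triangle of a symmetric
#' zero-diagonal matrix in the canonical row-major edge order;
#' `matricizeVector()` is its exact inverse. A 116-region matrix yields a
#' 6670-dimensional edge vector.
#'
#' @param m symmetric numeric matrix with zero diagonal.
#' @param checkSymmetry verify symmetry (tolerance 1e-12) and zero diagonal.
#' @return `vectorizeMatrix()`: numeric vector of length N(N-1)/2, named
#'   "labelI--labelJ" when `m` has dimnames.
#' @examples
#' m <- matrix(0, 3, 3); m[1, 2] <- m[2, 1] <- 0.5; m[2, 3] <- m[3, 2] <- -0.2
#' v <- vectorizeMatrix(m)
#' all.equal(matricizeVector(v), m)
#' @export
vectorizeMatrix <- function(m, checkSymmetry = TRUE) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("m must be a square matrix")
  if (checkSymmetry) {
    if (max(abs(m - t(m))) > 1e-12) stop("m is not symmetric within 1e-12")
    if (any(diag(m) != 0)) stop("m must have an exactly zero diagonal")
  }
  v <- t(m)[lower.tri(m)]
  if (!is.null(rownames(m))) {
    map <- edgeIndexMap(nrow(m))
    names(v) <- paste0(rownames(m)[map[, "i"]], "--", rownames(m)[map[, "j"]])
  }
  v
}

#' @rdname vectorizeMatrix
#' @param v numeric edge vector of triangular-number length.
#' @param regionLabels optional character vector of region names for the
#'   result's dimnames.
#' @return `matricizeVector()`: the symmetric zero-diagonal N x N matrix.
#' @export
matricizeVector <- function(v, regionLabels = NULL) {
  n <- .nRegionsFromEdges(length(v))
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- v    # fills column-major lower = row-major upper
  m <- t(m)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  if (!is.null(regionLabels)) {
    if (length(regionLabels) != n) stop("need ", n, " region labels")
    dimnames(m) <- list(regionLabels, regionLabels)
  }
  m
}

.checkCount <- function(x, what, min = 0L) {
  if (length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    stop(what, " must be a single integer >= ", min)
  }
  as.integer(x)
}
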