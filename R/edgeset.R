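#' Construct an EdgeSet
#'
#' @param pairs 2-column matrix of region index pairs (any order; rows are
#'   canonicalized to i < j), or a length-0 object for the empty set.
#' @param nRegions region universe size.
#' @param regionLabels optional region names (length nRegions).
#' @param provenance optional per-edge character tag.
#' @return an [EdgeSet-class] object.
#' @examples
#' EdgeSet(rbind(c(1, 2), c(3, 2)), nRegions = 4)
#' @export
EdgeSet <- function(pairs, nRegions, regionLabels = character(),
                    provenance = character()) {
  if (is.null(pairs) || length(pairs) == 0L) {
    pairs <- matrix(integer(), 0L, 2L)
  }
  pairs <- matrix(as.integer(pairs), ncol = 2L,
                  dimnames = list(NULL, c("i", "j")))
  if (nrow(pairs)) {
    pairs <- cbind(i = pmin(pairs[, 1], pairs[, 2]),
                   j = pmax(pairs[, 1], pairs[, 2]))
    ord <- order(pairs[, 1], pairs[, 2])
    pairs <- pairs[ord, , drop = FALSE]
    if (length(provenance)) provenance <- provenance[ord]
  }
  new("EdgeSet", pairs = pairs, nRegions = as.integer(nRegions),
      regionLabels = as.character(regionLabels),
      provenance = as.character(provenance))
}

#' Build an EdgeSet from canonical edge indices
#' @param indices integer vector of edge indices (1..E).
#' @inheritParams EdgeSet
#' @export
edgeSetFromIndices <- function(indices, nRegions, regionLabels = character()) {
  map <- edgeIndexMap(nRegions)
  EdgeSet(map[as.integer(indices), , drop = FALSE], nRegions, regionLabels)
}

#' @describeIn EdgeSet-class the i < j pair matrix.
#' @param x,object an EdgeSet.
#' @export
edgePairs <- function(x) x@pairs

#' @describeIn EdgeSet-class canonical edge indices (1..E) of the set.
#' @export
edgeIndices <- function(x) {
  p <- x@pairs
  if (!nrow(p)) return(integer())
  edgeIndex(p[, 1], p[, 2], x@nRegions)
}

#' @describeIn EdgeSet-class distinct regions touched by the set.
#' @export
edgeNodes <- function(x) sort(unique(as.integer(x@pairs)))

#' @describeIn EdgeSet-class per-edge provenance tags (may be empty).
#' @export
edgeProvenance <- function(x) x@provenance

#' @rdname nRegions
#' @export
setMethod("nRegions", "EdgeSet", function(x) x@nRegions)

#' @rdname regionLabels
#' @export
setMethod("regionLabels", "EdgeSet", function(x) x@regionLabels)

#' @describeIn EdgeSet-class number of edges in the set.
#' @export
setMethod("length", "EdgeSet", function(x) nrow(x@pairs))

#' @describeIn EdgeSet-class human-readable edge labels "A--B".
#' @export
edgeLabelsOf <- function(x) {
  p <- x@pairs
  if (!nrow(p)) return(character())
  lab <- if (length(x@regionLabels)) x@regionLabels else
    paste0("R", seq_len(x@nRegions))
  paste0(lab[p[, 1]], "--", lab[p[, 2]])
}

setMethod("show", "EdgeSet", function(object) {
  cat("EdgeSet:", length(object), "edges over", object@nRegions,
      "regions,", length(edgeNodes(object)), "nodes\n")
  if (length(object)) {
    lab <- edgeLabelsOf(object)
    k <- min(6L, length(lab))
    cat("  ", paste(lab[seq_len(k)], collapse = ", "),
        if (length(lab) > k) ", ..." else "", "\n", sep = "")
  }
})

#' Set operations on EdgeSets
#'
#' Intersection and difference over the same region universe.
#' @param a,b EdgeSets with identical `nRegions`.
#' @return an EdgeSet.
#' @export
intersectEdges <- function(a, b) {
  .sameUniverse(a, b)
  edgeSetFromIndices(intersect(edgeIndices(a), edgeIndices(b)),
                     nRegions(a), .pickLabels(a, b))
}

#' @rdname intersectEdges
#' @export
setdiffEdges <- function(a, b) {
  .sameUniverse(a, b)
  edgeSetFromIndices(setdiff(edgeIndices(a), edgeIndices(b)),
                     nRegions(a), .pickLabels(a, b))
}

.sameUniverse <- function(a, b) {
  if (nRegions(a) != nRegions(b)) {
    stop("edge sets live on different region universes (",
         nRegions(a), " vs ", nRegions(b), " regions)")
  }
  invisible(TRUE)
}

.pickLabels <- function(a, b) {
  if (length(regionLabels(a))) regionLabels(a) else regionLabels(b)
}
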