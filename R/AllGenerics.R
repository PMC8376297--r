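#' Region universe size
#' @param x an object with a region universe (EdgeSet, cohort, ...).
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))

#' Region labels
#' @param x an object carrying region names.
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))

#' Network strength: mean Fisher-z over a fixed edge set
#'
#' @param x a symmetric zero-diagonal z matrix, an E x S edge matrix, or a
#'   [ConnectomeCohort-class].
#' @param edges a non-empty [EdgeSet-class].
#' @return a single strength for a matrix, or one per subject for a cohort
#'   or edge matrix.
#' @export
setGeneric("networkStrength", function(x, edges)
  standardGeneric("networkStrength"))
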