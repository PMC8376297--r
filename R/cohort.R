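#' Construct a ConnectomeCohort
#'
#' Packs per-subject Fisher-z connectivity into the cohort container used by
#' all group-level analyses: one column per subject-session, one row per
#' canonical upper-triangle edge.
#'
#' @param matrices named list of symmetric zero-diagonal N x N Fisher-z
#'   matrices, or an E x S edge matrix already in canonical row order.
#' @param phenotype data.frame with one row per matrix: columns `subject`,
#'   `group`, `session`, and optionally `NCT` (seconds), `DST` (count).
#' @param nRegions required when `matrices` is an edge matrix.
#' @param regionLabels optional region names.
#' @param truth optional simulation ground-truth list.
#' @return a [ConnectomeCohort-class].
#' @export
ConnectomeCohort <- function(matrices, phenotype, nRegions = NULL,
                             regionLabels = NULL, truth = list()) {
  if (is.list(matrices)) {
    if (!length(matrices)) stop("no matrices supplied")
    n <- nrow(matrices[[1]])
    z <- vapply(matrices, vectorizeMatrix, numeric(nEdges(n)))
    if (is.null(regionLabels) && !is.null(rownames(matrices[[1]]))) {
      regionLabels <- rownames(matrices[[1]])
    }
    nRegions <- n
  } else {
    z <- as.matrix(matrices)
    if (is.null(nRegions)) nRegions <- .nRegionsFromEdges(nrow(z))
    if (nrow(z) != nEdges(nRegions)) {
      stop("edge matrix has ", nrow(z), " rows; expected ", nEdges(nRegions))
    }
  }
  phenotype <- as.data.frame(phenotype)
  if (nrow(phenotype) != ncol(z)) {
    stop("phenotype rows (", nrow(phenotype), ") must match subjects (",
         ncol(z), ")")
  }
  for (col in c("NCT", "DST")) {
    if (is.null(phenotype[[col]])) phenotype[[col]] <- NA_real_
  }
  cn <- paste(phenotype$subject, phenotype$session, sep = "_")
  colnames(z) <- cn
  se <- SummarizedExperiment(
    assays = list(z = z),
    colData = DataFrame(phenotype, row.names = cn),
    metadata = list(nRegions = as.integer(nRegions),
                    regionLabels = as.character(regionLabels %||% character()),
                    truth = truth)
  )
  new("ConnectomeCohort", se)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname nRegions
#' @export
setMethod("nRegions", "ConnectomeCohort",
          function(x) metadata(x)$nRegions)

#' @rdname regionLabels
#' @export
setMethod("regionLabels", "ConnectomeCohort",
          function(x) metadata(x)$regionLabels)

#' Fisher-z edge matrix of a cohort (E x S)
#' @param x a [ConnectomeCohort-class].
#' @export
edgeMatrix <- function(x) assay(x, "z")

#' Phenotype table of a cohort
#' @param x a [ConnectomeCohort-class].
#' @return base data.frame (subject, group, session, NCT, DST, ...).
#' @export
phenotype <- function(x) as.data.frame(colData(x))

#' Simulation ground truth stored with a cohort
#' @param x a [ConnectomeCohort-class].
#' @export
cohortTruth <- function(x) metadata(x)$truth

#' One subject-session's connectivity matrix
#' @param x a [ConnectomeCohort-class].
#' @param which column index or column name ("subject_session").
#' @return symmetric zero-diagonal N x N matrix.
#' @export
subjectMatrix <- function(x, which) {
  lab <- regionLabels(x)
  matricizeVector(edgeMatrix(x)[, which],
                  if (length(lab)) lab else NULL)
}

#' Subset a cohort by phenotype
#'
#' @param x a [ConnectomeCohort-class].
#' @param group,session optional values to keep.
#' @return a [ConnectomeCohort-class] with the matching columns.
#' @export
subsetCohort <- function(x, group = NULL, session = NULL) {
  keep <- rep(TRUE, ncol(x))
  ph <- phenotype(x)
  if (!is.null(group)) keep <- keep & ph$group %in% group
  if (!is.null(session)) keep <- keep & ph$session %in% session
  if (!any(keep)) stop("no subjects match the requested group/session")
  x[, keep]
}

setMethod("show", "ConnectomeCohort", function(object) {
  ph <- phenotype(object)
  cat("ConnectomeCohort:", ncol(object), "subject-sessions,",
      nRegions(object), "regions (", nrow(object), "edges )\n")
  print(table(group = ph$group, session = ph$session))
  tr <- cohortTruth(object)
  if (length(tr)) cat("ground truth recorded:",
                      paste(names(tr), collapse = ", "), "\n")
})
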