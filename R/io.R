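# sniff comma vs tab on the first line
.sniffSep <- function(path) {
  line <- readLines(path, n = 1L)
  if (lengths(regmatches(line, gregexpr("\t", line))) > 0) "\t" else ","
}

.readDelim <- function(path) {
  sep <- .sniffSep(path)
  first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  hasHeader <- anyNA(suppressWarnings(as.numeric(first)))
  tab <- utils::read.table(path, sep = sep, header = hasHeader,
                           check.names = FALSE)
  m <- as.matrix(tab)
  if (!hasHeader) dimnames(m) <- NULL   # drop read.table's V1.. autonames
  m
}

#' Read / write connectivity matrices and ROI time series
#'
#' Delimited text (comma or tab, sniffed), with an optional header row of
#' region labels. Matrices are validated as square and symmetric; the
#' diagonal is forced to exactly 0.
#'
#' @param path file path.
#' @return `readConnectivityMatrix()`: symmetric zero-diagonal matrix.
#' @export
readConnectivityMatrix <- function(path) {
  m <- .readDelim(path)
  if (nrow(m) != ncol(m)) {
    stop(path, ": matrix is ", nrow(m), " x ", ncol(m), ", not square")
  }
  if (max(abs(m - t(m))) > 1e-8) stop(path, ": matrix is not symmetric")
  if (!is.null(colnames(m))) rownames(m) <- colnames(m)
  diag(m) <- 0
  m
}

#' @rdname readConnectivityMatrix
#' @param samplingInterval seconds per volume attached to the result.
#' @return `readRoiTimeSeries()`: T x N matrix (see [roiTimeSeries()]).
#' @export
readRoiTimeSeries <- function(path, samplingInterval = 2.5) {
  roiTimeSeries(.readDelim(path), samplingInterval = samplingInterval)
}

#' @rdname readConnectivityMatrix
#' @param m matrix to write.
#' @export
writeConnectivityMatrix <- function(m, path) {
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = !is.null(colnames(m)))
  invisible(path)
}

#' Read a phenotype table
#'
#' TSV with columns subject, group, session and (optionally) NCT, DST.
#' @param path file path.
#' @export
readPhenotype <- function(path) {
  ph <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("subject", "group", "session")
  miss <- setdiff(need, colnames(ph))
  if (length(miss)) {
    stop("phenotype table lacks column(s): ", paste(miss, collapse = ", "))
  }
  ph
}

#' Write an edge vector as a two-column TSV
#'
#' Columns: edge label ("regionA--regionB") and Fisher-z value.
#' @param v named numeric edge vector (names as produced by
#'   [vectorizeMatrix()] on a labeled matrix), or unnamed with
#'   `regionLabels` given.
#' @param path output path.
#' @param regionLabels labels used to construct edge names when `v` is
#'   unnamed.
#' @export
writeEdgeVector <- function(v, path, regionLabels = NULL) {
  if (is.null(names(v))) {
    n <- .nRegionsFromEdges(length(v))
    lab <- regionLabels %||% paste0("R", seq_len(n))
    map <- edgeIndexMap(n)
    names(v) <- paste0(lab[map[, 1]], "--", lab[map[, 2]])
  }
  utils::write.table(data.frame(edge = names(v), z = as.numeric(v)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an edge set as a TSV edge list
#' @param edges an [EdgeSet-class].
#' @param path output path.
#' @export
writeEdgeList <- function(edges, path) {
  p <- edgePairs(edges)
  lab <- if (length(regionLabels(edges))) regionLabels(edges) else
    paste0("R", seq_len(nRegions(edges)))
  df <- data.frame(regionA = lab[p[, 1]], regionB = lab[p[, 2]])
  if (length(edgeProvenance(edges))) df$provenance <- edgeProvenance(edges)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# edge set <-> 0-based pair list for JSON truth files
.edgeSetToJson <- function(es) {
  p <- edgePairs(es)
  lapply(seq_len(nrow(p)), function(k) c(p[k, 1] - 1L, p[k, 2] - 1L))
}

.edgeSetFromJson <- function(lst, nRegions, regionLabels = character()) {
  if (!length(lst)) return(EdgeSet(NULL, nRegions, regionLabels))
  EdgeSet(do.call(rbind, lapply(lst, as.integer)) + 1L, nRegions,
          regionLabels)
}

#' Write a cohort to a directory
#'
#' One connectivity-matrix TSV per subject-session
#' (`<subject>_<session>.tsv`), a phenotype TSV (subject, group, session,
#' NCT, DST) and, when ground truth is present, a `truth.json` with the
#' planted edge lists (0-based node pairs) and coefficients.
#'
#' @param cohort a [ConnectomeCohort-class].
#' @param dir output directory (created if needed).
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ph <- phenotype(cohort)
  for (k in seq_len(ncol(cohort))) {
    writeConnectivityMatrix(
      subjectMatrix(cohort, k),
      file.path(dir, paste0(ph$subject[k], "_", ph$session[k], ".tsv")))
  }
  utils::write.table(ph[, c("subject", "group", "session", "NCT", "DST")],
                     file.path(dir, "phenotype.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tr <- cohortTruth(cohort)
  if (length(tr)) {
    out <- list(
      nRegions = nRegions(cohort),
      disruptedEdges = .edgeSetToJson(tr$disruptedEdges),
      hyperEdges = .edgeSetToJson(tr$hyperEdges),
      pmnEdges = .edgeSetToJson(tr$pmnEdges),
      deltaZ = tr$deltaZ, hyperDeltaZ = tr$hyperDeltaZ,
      couplingBeta = tr$couplingBeta,
      moderationGamma = tr$moderationGamma,
      referenceGroup = tr$referenceGroup
    )
    jsonlite::write_json(out, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a cohort from a directory written by [writeCohort()]
#'
#' @param dir directory containing `phenotype.tsv` and per-subject matrix
#'   TSVs; `truth.json` is restored when present.
#' @return a [ConnectomeCohort-class].
#' @export
readCohort <- function(dir) {
  ph <- readPhenotype(file.path(dir, "phenotype.tsv"))
  mats <- lapply(seq_len(nrow(ph)), function(k) {
    f <- file.path(dir, paste0(ph$subject[k], "_", ph$session[k], ".tsv"))
    if (!file.exists(f)) stop("missing matrix file: ", f)
    readConnectivityMatrix(f)
  })
  truth <- list()
  tf <- file.path(dir, "truth.json")
  if (file.exists(tf)) {
    tr <- jsonlite::read_json(tf)
    n <- tr$nRegions
    lab <- rownames(mats[[1]]) %||% character()
    truth <- list(
      disruptedEdges = .edgeSetFromJson(tr$disruptedEdges, n, lab),
      hyperEdges = .edgeSetFromJson(tr$hyperEdges, n, lab),
      pmnEdges = .edgeSetFromJson(tr$pmnEdges, n, lab),
      deltaZ = tr$deltaZ, hyperDeltaZ = tr$hyperDeltaZ,
      couplingBeta = tr$couplingBeta,
      moderationGamma = tr$moderationGamma,
      referenceGroup = tr$referenceGroup
    )
  }
  ConnectomeCohort(mats, ph, truth = truth)
}
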