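#' ROI time-series container
#'
#' BOLD time series are carried as plain T x N numeric matrices (rows =
#' timepoints, columns = regions) with a `samplingInterval` attribute in
#' seconds and optional column names as region labels. `roiTimeSeries()`
#' attaches and validates those pieces.
#'
#' @param values T x N numeric matrix.
#' @param samplingInterval seconds between volumes (repetition time);
#'   default 2.5 s.
#' @param regionLabels optional N region names.
#' @export
roiTimeSeries <- function(values, samplingInterval = 2.5,
                          regionLabels = NULL) {
  values <- as.matrix(values)
  if (nrow(values) < 2L || ncol(values) < 2L) {
    stop("need at least 2 timepoints and 2 regions")
  }
  if (!all(is.finite(values))) stop("time series contain non-finite values")
  if (!is.null(regionLabels)) colnames(values) <- regionLabels
  attr(values, "samplingInterval") <- samplingInterval
  values
}

.samplingInterval <- function(ts, samplingInterval = NULL) {
  samplingInterval %||% attr(ts, "samplingInterval") %||% 2.5
}

#' Linear detrend and zero-phase band-pass filter
#'
#' Removes each region's least-squares linear trend, then applies a
#' forward-backward (zero-phase) Butterworth band-pass, order 2 per pass.
#' Defaults retain the 0.01-0.08 Hz band conventionally used for
#' resting-state BOLD fluctuations.
#'
#' @param ts T x N matrix (see [roiTimeSeries()]).
#' @param lowHz,highHz pass-band edges in Hz; must satisfy
#'   `0 <= lowHz < highHz < 1/(2 * samplingInterval)` (the Nyquist
#'   frequency).
#' @param samplingInterval seconds per sample; taken from `ts` when absent.
#' @param order Butterworth order per pass.
#' @return filtered matrix, same shape and attributes.
#' @export
detrendBandpass <- function(ts, lowHz = 0.01, highHz = 0.08,
                            samplingInterval = NULL, order = 2L) {
  dt <- .samplingInterval(ts, samplingInterval)
  nyquist <- 1 / (2 * dt)
  if (lowHz < 0 || lowHz >= highHz) stop("need 0 <= lowHz < highHz")
  if (highHz >= nyquist) {
    stop("highHz (", highHz, " Hz) must be below the Nyquist frequency ",
         signif(nyquist, 4), " Hz")
  }
  T <- nrow(ts)
  # filtfilt pads with 3x the filter length; order-2 bandpass has 5 taps
  minT <- 3L * (4L * order + 1L)
  if (T < minT) stop("need at least ", minT, " timepoints for filter order ",
                     order, "; got ", T)
  detr <- stats::lm.fit(cbind(1, seq_len(T)), ts)$residuals
  bf <- signal::butter(order, c(lowHz, highHz) / nyquist, type = "pass")
  # odd-reflection padding to full length before the forward-backward pass:
  # keeps filter transients out of the retained segment and makes the
  # operation symmetric under time reversal
  npad <- T - 1L
  out <- apply(detr, 2L, function(x) {
    padded <- c(2 * x[1] - x[(npad + 1L):2],
                x,
                2 * x[T] - x[(T - 1L):(T - npad)])
    signal::filtfilt(bf, padded)[(npad + 1L):(npad + T)]
  })
  dimnames(out) <- dimnames(ts)
  attr(out, "samplingInterval") <- dt
  out
}

#' Regress nuisance signals out of ROI time series
#'
#' Each region's series is replaced by the residual of a least-squares
#' projection onto an intercept, the confound columns, and their
#' backward-difference temporal derivatives (first sample padded with 0).
#' Typical confounds: mean white-matter and CSF signals and six head-motion
#' parameters.
#'
#' @param ts T x N matrix.
#' @param confounds T x C numeric matrix.
#' @param addDerivatives include backward-difference derivatives.
#' @return residual matrix, same shape; residuals are orthogonal to the
#'   design within 1e-8.
#' @export
regressNuisance <- function(ts, confounds, addDerivatives = TRUE) {
  confounds <- as.matrix(confounds)
  if (nrow(confounds) != nrow(ts)) {
    stop("confounds must have one row per timepoint (", nrow(ts), ")")
  }
  if (ncol(confounds) < 1L) stop("need at least one confound column")
  X <- cbind(intercept = 1, confounds)
  if (addDerivatives) {
    d <- rbind(0, diff(confounds))
    colnames(d) <- paste0(colnames(confounds) %||%
                            paste0("C", seq_len(ncol(confounds))), "_deriv")
    X <- cbind(X, d)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])
    warning("nuisance design is rank deficient; dropping ", length(drop),
            " dependent column(s)")
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    qrX <- qr(X)
  }
  out <- ts - X %*% qr.coef(qrX, ts)
  dimnames(out) <- dimnames(ts)
  attr(out, "samplingInterval") <- attr(ts, "samplingInterval")
  out
}

#' Fisher-z functional connectivity matrix
#'
#' Pearson correlation between every pair of region time series, Fisher
#' z-transformed (`atanh`), with an exactly zero diagonal. Correlations are
#' clipped to +/-(1 - 1e-10) before the transform so z stays finite; a
#' message reports when clipping triggers.
#'
#' @param ts T x N matrix with T >= 3.
#' @param clipBound clip correlations into (-clipBound, clipBound).
#' @return symmetric N x N Fisher-z matrix with zero diagonal, region
#'   labels as dimnames when available.
#' @examples
#' set.seed(1)
#' z <- connectivityMatrix(matrix(rnorm(300), 100, 3))
#' @export
connectivityMatrix <- function(ts, clipBound = 1 - 1e-10) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3L) stop("need at least 3 timepoints for correlation")
  sds <- apply(ts, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(ts)[sds == 0] %||% which(sds == 0)
    stop("zero-variance region(s): ", paste(bad, collapse = ", "))
  }
  r <- stats::cor(ts)
  offdiag <- r[row(r) != col(r)]
  if (any(abs(offdiag) >= clipBound)) {
    message("clipped ", sum(abs(offdiag) >= clipBound) / 2,
            " correlation(s) at +/-", format(clipBound))
  }
  r <- pmin(pmax(r, -clipBound), clipBound)
  z <- atanh(r)
  diag(z) <- 0
  z
}

#' Full temporal preprocessing chain
#'
#' Convenience wrapper running linear detrend + band-pass and nuisance
#' regression in either order. The default order (filter, then nuisance
#' regression) follows the listing convention of resting-state pipelines
#' that filter first; `order = "regress_first"` swaps the two.
#'
#' @inheritParams detrendBandpass
#' @param confounds optional T x C confound matrix; skipped when NULL.
#' @param order "bandpass_first" (default) or "regress_first".
#' @return preprocessed T x N matrix.
#' @export
preprocessTimeSeries <- function(ts, confounds = NULL, lowHz = 0.01,
                                 highHz = 0.08, samplingInterval = NULL,
                                 order = c("bandpass_first",
                                           "regress_first")) {
  order <- match.arg(order)
  steps <- list(
    bp = function(x) detrendBandpass(x, lowHz, highHz, samplingInterval),
    nr = function(x) if (is.null(confounds)) x else
      regressNuisance(x, confounds)
  )
  if (order == "bandpass_first") steps$nr(steps$bp(ts))
  else steps$bp(steps$nr(ts))
}
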