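#' Two-sample t test on raw data
#'
#' Thin wrapper over [stats::t.test()] returning (t, df, p), used for
#' behavior-score and network-strength group comparisons. Degenerate input
#' (zero variance in both samples with equal means) yields t = 0, p = 1.
#'
#' @param a,b numeric vectors (length >= 2 each).
#' @param tails "two" or "one" (one-tailed tests mean(a) > mean(b)).
#' @param variance "pooled" (Student) or "welch".
#' @return list(t, df, p).
#' @export
twoSampleT <- function(a, b, tails = c("two", "one"),
                       variance = c("pooled", "welch")) {
  tails <- match.arg(tails)
  variance <- match.arg(variance)
  if (length(a) < 2L || length(b) < 2L) stop("both samples need >= 2 values")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = length(a) + length(b) - 2L, p = 1))
    }
    tv <- Inf * sign(mean(a) - mean(b))
    return(list(t = tv, df = length(a) + length(b) - 2L,
                p = if (tails == "two" || tv > 0) 0 else 1))
  }
  ht <- stats::t.test(a, b, var.equal = (variance == "pooled"),
                      alternative = if (tails == "two") "two.sided"
                                    else "greater")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Two-sample t test from summary statistics
#'
#' Recomputes the two-sample t from printed group means, SDs and sizes
#' (pooled-variance Student or Welch), enabling checks against published
#' "mean +/- SD" tables.
#'
#' @param meanA,sdA,nA,meanB,sdB,nB group summaries (sd > 0, n >= 2).
#' @inheritParams twoSampleT
#' @return list(t, df, p).
#' @examples
#' summaryT(40.4, 10.2, 32, 56.5, 32.1, 36)
#' @export
summaryT <- function(meanA, sdA, nA, meanB, sdB, nB,
                     tails = c("two", "one"),
                     variance = c("pooled", "welch")) {
  tails <- match.arg(tails)
  variance <- match.arg(variance)
  if (sdA <= 0 || sdB <= 0) stop("SDs must be positive")
  if (nA < 2L || nB < 2L) stop("group sizes must be >= 2")
  if (variance == "pooled") {
    sp2 <- ((nA - 1) * sdA^2 + (nB - 1) * sdB^2) / (nA + nB - 2)
    se <- sqrt(sp2 * (1 / nA + 1 / nB))
    df <- nA + nB - 2
  } else {
    se <- sqrt(sdA^2 / nA + sdB^2 / nB)
    df <- (sdA^2 / nA + sdB^2 / nB)^2 /
      ((sdA^2 / nA)^2 / (nA - 1) + (sdB^2 / nB)^2 / (nB - 1))
  }
  t <- (meanA - meanB) / se
  p <- if (tails == "two") 2 * stats::pt(abs(t), df, lower.tail = FALSE)
       else stats::pt(t, df, lower.tail = FALSE)
  list(t = t, df = df, p = p)
}

# bias-corrected percentile interval from a bootstrap sample
.bcInterval <- function(boot, estimate, level) {
  boot <- boot[is.finite(boot)]
  B <- length(boot)
  prop <- (sum(boot < estimate) + 0.5 * sum(boot == estimate)) / B
  prop <- min(max(prop, 1 / (B + 1)), B / (B + 1))
  z0 <- stats::qnorm(prop)
  zl <- stats::qnorm((1 - level) / 2)
  probs <- stats::pnorm(c(2 * z0 + zl, 2 * z0 - zl))
  unname(stats::quantile(boot, probs, type = 6))
}

#' Moderated regression with bias-corrected bootstrap CIs
#'
#' Ordinary least squares fit of
#' `score ~ 1 + strength + moderator + strength:moderator`, with
#' bias-corrected (BC, not accelerated) percentile bootstrap confidence
#' intervals for every unstandardized coefficient from nonparametric case
#' resampling, and the OLS t-test p value for the interaction. Tests
#' whether group membership changes the brain-behavior slope.
#'
#' Strength and moderator are mean-centered before forming the interaction
#' by default (this shifts only the lower-order coefficients, never the
#' interaction term). Bootstrap resamples in which one moderator level is
#' absent are redrawn; the redraw count is recorded.
#'
#' @param score,strength numeric vectors.
#' @param moderator binary vector (two levels, each with >= 3 subjects).
#' @param nBoot bootstrap resamples (default 10000).
#' @param ciLevel confidence level (default 0.95).
#' @param seed RNG seed.
#' @param center mean-center strength and moderator first.
#' @return a [ModerationResult-class].
#' @export
moderatedRegression <- function(score, strength, moderator,
                                nBoot = 10000L, ciLevel = 0.95,
                                seed = 1L, center = TRUE) {
  n <- length(score)
  if (length(strength) != n || length(moderator) != n) {
    stop("score, strength and moderator must have equal length")
  }
  lev <- unique(moderator)
  if (length(lev) != 2L) {
    stop("moderator must take exactly two values (got ",
         length(lev), ")")
  }
  if (min(table(moderator)) < 3L) {
    stop("both moderator levels need >= 3 subjects")
  }
  g <- as.numeric(as.character(moderator) == sort(as.character(lev))[2])
  if (center) {
    strengthC <- strength - mean(strength)
    gC <- g - mean(g)
  } else {
    strengthC <- strength; gC <- g
  }
  X <- cbind(intercept = 1, strength = strengthC, moderator = gC,
             interaction = strengthC * gC)
  fit <- stats::lm.fit(X, score)
  est <- fit$coefficients
  sigma2 <- sum(fit$residuals^2) / (n - 4L)
  XtXinv <- chol2inv(chol(crossprod(X)))
  seInt <- sqrt(sigma2 * XtXinv[4, 4])
  tInt <- est[4] / seInt
  interactionP <- 2 * stats::pt(abs(tInt), df = n - 4L, lower.tail = FALSE)

  nBoot <- .checkCount(nBoot, "nBoot", min = 1L)
  set.seed(.checkCount(seed, "seed"))
  boot <- matrix(NA_real_, nBoot, 4L)
  nRedraws <- 0L
  for (b in seq_len(nBoot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(moderator[idx])) == 2L) break
      nRedraws <- nRedraws + 1L
    }
    boot[b, ] <- stats::lm.fit(X[idx, , drop = FALSE],
                               score[idx])$coefficients
  }
  ci <- t(vapply(1:4, function(j) .bcInterval(boot[, j], est[j], ciLevel),
                 numeric(2)))
  dimnames(ci) <- list(names(est), c("lower", "upper"))
  new("ModerationResult",
      coefficients = est, ci = ci, interactionP = unname(interactionP),
      nBoot = nBoot, ciLevel = ciLevel, seed = as.integer(seed),
      nRedraws = nRedraws)
}

setMethod("show", "ModerationResult", function(object) {
  cat(sprintf(
    "Moderated regression (%d bootstrap resamples, %.0f%% BC CIs)\n",
    object@nBoot, 100 * object@ciLevel))
  out <- data.frame(estimate = object@coefficients,
                    lower = object@ci[, 1], upper = object@ci[, 2])
  print(round(out, 4))
  cat(sprintf("interaction p (OLS t test) = %.4g\n", object@interactionP))
  if (object@nRedraws > 0) {
    cat(object@nRedraws, "bootstrap resample(s) redrawn",
        "(single moderator level)\n")
  }
})
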