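# Regression and classification metrics, ROC with optimal operating point,
# bootstrap confidence intervals, and the majority-class null model.

#' Spearman correlation and coefficient of determination
#'
#' Spearman rank-order correlation (average ranks for ties) between
#' predictions and observations, and R^2 = 1 - SS_res/SS_tot computed on the
#' configured scale (log10 by default, matching the training target).
#'
#' @param pred,obs viscosities in cP (length >= 3)
#' @param scale \code{"log10"} or \code{"raw"} for R^2
#' @return list(spearman, r2)
#' @export
regressionMetrics <- function(pred, obs, scale = "log10") {
  if (length(pred) != length(obs)) stop("length mismatch")
  if (length(obs) < 3) stop("need at least 3 observations")
  if (stats::sd(obs) == 0) stop("constant observations: metrics undefined")
  rho <- stats::cor(pred, obs, method = "spearman")
  p <- applyTransform(pred, scale)
  o <- applyTransform(obs, scale)
  r2 <- 1 - sum((o - p)^2) / sum((o - mean(o))^2)
  list(spearman = rho, r2 = r2)
}

#' ROC analysis with optimal operating point
#'
#' Classes are defined by the viscosity cutoff (viscous when observed
#' viscosity >= cutoff; 20 cP by default).  The ROC curve sweeps all
#' prediction thresholds; AUC is the trapezoid area.  The optimal operating
#' point is the threshold closest to the (FPR 0, TPR 1) corner (ties to the
#' higher TPR); Youden's J is available as an alternative.  The confusion
#' matrix and accuracy at the OOP cutoff are returned.
#'
#' @param pred predicted viscosities in cP
#' @param obs observed viscosities in cP (both classes must be present)
#' @param classCutoff class-defining viscosity (cP)
#' @param oop \code{"corner"} (default) or \code{"youden"}
#' @return list(auc, oopCutoff, confusion (2x2), accuracy, tpr, fpr,
#'   thresholds)
#' @export
rocAnalysis <- function(pred, obs, classCutoff = 20, oop = c("corner", "youden")) {
  oop <- match.arg(oop)
  truth <- obs >= classCutoff
  if (all(truth) || !any(truth)) stop("single observed class: ROC undefined")
  nPos <- sum(truth); nNeg <- sum(!truth)
  thr <- c(-Inf, sort(unique(pred)), Inf)
  tpr <- vapply(thr, function(t) sum(pred >= t & truth) / nPos, 1.0)
  fpr <- vapply(thr, function(t) sum(pred >= t & !truth) / nNeg, 1.0)
  ord <- order(fpr, tpr)
  auc <- sum(diff(fpr[ord]) * (utils::head(tpr[ord], -1) + utils::tail(tpr[ord], -1)) / 2)
  finite <- is.finite(thr)
  crit <- if (oop == "corner") -(fpr^2 + (1 - tpr)^2) else tpr - fpr
  cand <- which(finite)
  best <- cand[order(-crit[cand], -tpr[cand], thr[cand])][1]
  cutoff <- thr[best]
  predPos <- pred >= cutoff
  confusion <- matrix(c(sum(predPos & truth), sum(predPos & !truth),
                        sum(!predPos & truth), sum(!predPos & !truth)),
                      2, 2, byrow = TRUE,
                      dimnames = list(predicted = c("viscous", "nonviscous"),
                                      observed = c("viscous", "nonviscous")))
  list(auc = auc, oopCutoff = cutoff, confusion = confusion,
       accuracy = (confusion[1, 1] + confusion[2, 2]) / length(obs),
       tpr = tpr, fpr = fpr, thresholds = thr, oopMethod = oop)
}

#' Percentile bootstrap confidence interval
#'
#' Paired resampling with replacement; resamples on which the metric is
#' undefined (error) are skipped and counted.  Deterministic given the seed.
#'
#' @param metricFn function(pred, obs) returning a single number
#' @param pred,obs paired vectors
#' @param n bootstrap resamples (default 500)
#' @param seed RNG seed
#' @param level confidence level (default 0.95)
#' @return c(low, high) with attributes \code{point} and \code{nUndefined}
#' @export
bootstrapCI <- function(metricFn, pred, obs, n = 500L, seed = 1L, level = 0.95) {
  if (n < 100) stop("use at least 100 resamples")
  point <- metricFn(pred, obs)
  vals <- withSeed(seed, {
    vapply(seq_len(n), function(b) {
      idx <- sample(length(pred), replace = TRUE)
      tryCatch(metricFn(pred[idx], obs[idx]), error = function(e) NA_real_)
    }, 1.0)
  })
  bad <- sum(is.na(vals))
  if (bad > n / 2) stop("confidence interval unstable: ", bad, " of ", n,
                        " resamples undefined")
  qs <- stats::quantile(vals[!is.na(vals)],
                        c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  structure(c(low = qs[1], high = qs[2]), point = point, nUndefined = bad)
}

#' Majority-class null model accuracy
#'
#' Accuracy of always predicting the majority viscosity class at the given
#' cutoff; an exact tie reports 0.5 with a \code{tie} attribute.
#'
#' @param obs observed viscosities in cP
#' @param classCutoff class-defining viscosity (cP)
#' @export
nullModelAccuracy <- function(obs, classCutoff = 20) {
  if (!length(obs)) stop("empty observations")
  nPos <- sum(obs >= classCutoff)
  nNeg <- length(obs) - nPos
  if (nPos == nNeg) return(structure(0.5, tie = TRUE))
  structure(max(nPos, nNeg) / length(obs), tie = FALSE)
}

#' Full metrics report
#'
#' Convenience wrapper: regression metrics, ROC analysis at the class cutoff,
#' null-model accuracy, and bootstrap confidence intervals for Spearman, R^2
#' and AUC.
#'
#' @inheritParams rocAnalysis
#' @param nBootstrap resamples for the confidence intervals
#' @param seed RNG seed
#' @param scale scale for R^2
#' @return nested list (a metrics report)
#' @export
metricsReport <- function(pred, obs, classCutoff = 20, nBootstrap = 500L,
                          seed = 1L, scale = "log10") {
  reg <- regressionMetrics(pred, obs, scale)
  roc <- rocAnalysis(pred, obs, classCutoff)
  list(spearman = reg$spearman, r2 = reg$r2, rocAuc = roc$auc,
       oopCutoff = roc$oopCutoff, confusion = roc$confusion,
       accuracy = roc$accuracy,
       nullAccuracy = as.numeric(nullModelAccuracy(obs, classCutoff)),
       ci = list(
         spearman = bootstrapCI(function(p, o) regressionMetrics(p, o, scale)$spearman,
                                pred, obs, nBootstrap, seed),
         r2 = bootstrapCI(function(p, o) regressionMetrics(p, o, scale)$r2,
                          pred, obs, nBootstrap, seed + 1L),
         auc = bootstrapCI(function(p, o) rocAnalysis(p, o, classCutoff)$auc,
                           pred, obs, nBootstrap, seed + 2L)),
       nBootstrap = nBootstrap)
}
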