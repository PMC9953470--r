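#' @include cnn.R
NULL

#' Sensitivity and specificity from one-vs-rest confusion counts
#'
#' Sensitivity = TP / (TP + FN); specificity = TN / (TN + FP).
#'
#' @param tp,fn,tn,fp non-negative confusion counts.
#' @return Named numeric \code{c(sensitivity = , specificity = )}.
#' @export
#' @examples
#' sensSpec(tp = 7, fn = 3, tn = 8, fp = 2)  # 0.7, 0.8
sensSpec <- function(tp, fn, tn, fp) {
  if (tp + fn == 0) stop("sensitivity undefined: no positive samples")
  if (tn + fp == 0) stop("specificity undefined: no negative samples")
  c(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
}

#' Positive and negative likelihood ratios with a guarded denominator
#'
#' LR+ = sensitivity / (1 - specificity), LR- = (1 - sensitivity) /
#' specificity. A small epsilon floors each denominator so a perfect
#' specificity (or zero specificity) yields a large finite ratio instead of
#' infinity; ratios are always computed from unrounded sensitivity and
#' specificity, never from rounded table-style values.
#'
#' @param sensitivity,specificity values in [0, 1].
#' @param eps denominator floor (default 1e-4).
#' @return Named numeric \code{c(lr_plus = , lr_minus = )}.
#' @export
#' @examples
#' likelihoodRatios(0.9, 0.8)     # 4.5, 0.125
#' likelihoodRatios(0.773, 1.0)   # guard active: LR+ = 7730
likelihoodRatios <- function(sensitivity, specificity, eps = 1e-4) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1, eps > 0)
  c(lr_plus = sensitivity / max(1 - specificity, eps),
    lr_minus = (1 - sensitivity) / max(specificity, eps))
}

# Mann-Whitney AUC of `scores` for positives vs negatives, ties counted 0.5.
aucMW <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: a class is empty")
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' One-vs-rest ROC AUC per risk class
#'
#' For each class c, the AUC of the class-c probability as a score for
#' "label == c" versus the rest, computed as the Mann-Whitney pair
#' statistic with ties counted one half (equivalently, the area under the
#' empirical ROC curve).
#'
#' @param probs numeric matrix [n x 3] of class probabilities, columns in
#'   the order high, intermediate, low.
#' @param labels factor/character of true classes.
#' @return Named numeric AUC per class; \code{NA} for a class absent from
#'   \code{labels}.
#' @export
rocAucOvr <- function(probs, labels) {
  labels <- factor(as.character(labels), levels = tdpRiskLevels())
  if (length(unique(labels)) < 2)
    stop("AUC undefined: labels contain a single class")
  vapply(seq_along(tdpRiskLevels()), function(ci) {
    pos <- labels == tdpRiskLevels()[ci]
    if (!any(pos)) return(NA_real_)
    aucMW(probs[, ci], pos)
  }, numeric(1)) |> stats::setNames(tdpRiskLevels())
}

#' Repeated resampled testing of a classifier
#'
#' The evaluation harness of the pipeline: for each of \code{n_repeats}
#' repeats, \code{per_drug} samples are drawn without replacement from each
#' drug's pool, predicted, reduced one-vs-rest per class, and scored (AUC,
#' sensitivity, specificity, LR+, LR-). Points are means over repeats with
#' central 95 percent percentile intervals (the production protocol runs
#' 10,000 repeats); the confusion matrix is averaged over repeats and
#' row-normalized. Deterministic for a given seed.
#'
#' @param model a trained \linkS4class{ConvNet}, or any function mapping a
#'   trace matrix to a probability matrix [n x 3] (useful for oracle /
#'   null-model baselines).
#' @param ds the test \linkS4class{APDataset}.
#' @param n_repeats number of resampled test sets.
#' @param per_drug samples drawn per drug per repeat (the harness's main
#'   free parameter).
#' @param seed integer seed.
#' @param eps likelihood-ratio denominator guard.
#' @return A \linkS4class{RiskEvalReport}.
#' @export
repeatedTest <- function(model, ds, n_repeats = 10000, per_drug = 100,
                         seed = 1, eps = 1e-4) {
  drugs <- as.character(SummarizedExperiment::colData(ds)$drug)
  labels <- riskClass(ds)
  pools <- split(seq_along(drugs), drugs)
  short <- names(pools)[vapply(pools, length, 1L) < per_drug]
  if (length(short))
    stop("drug(s) with fewer than per_drug = ", per_drug, " samples: ",
         paste(short, collapse = ", "))
  probs_all <- if (is.function(model)) {
    model(apTraces(ds))
  } else {
    as.matrix(predictRisk(model, ds)[, 1:3])
  }
  lev <- tdpRiskLevels()
  metric_names <- c("auc", "sensitivity", "specificity", "lr_plus",
                    "lr_minus")
  acc <- array(NA_real_, c(n_repeats, 3, length(metric_names)),
               dimnames = list(NULL, lev, metric_names))
  conf_sum <- matrix(0, 3, 3, dimnames = list(lev, lev))
  withLocalSeed(seed, {
    for (r in seq_len(n_repeats)) {
      idx <- unlist(lapply(pools, function(p) {
        p[sample.int(length(p), per_drug)]
      }), use.names = FALSE)
      pr <- probs_all[idx, , drop = FALSE]
      truth <- labels[idx]
      pred <- factor(lev[max.col(pr, ties.method = "first")], levels = lev)
      auc <- rocAucOvr(pr, truth)
      for (ci in 1:3) {
        pos <- truth == lev[ci]
        ppos <- pred == lev[ci]
        ss <- sensSpec(tp = sum(pos & ppos), fn = sum(pos & !ppos),
                       tn = sum(!pos & !ppos), fp = sum(!pos & ppos))
        lr <- likelihoodRatios(ss[1], ss[2], eps = eps)
        acc[r, ci, ] <- c(auc[ci], ss, lr)
      }
      cm <- matrix(table(truth, pred), 3, 3)
      conf_sum <- conf_sum + cm / rowSums(cm)
    }
  })
  met <- do.call(rbind, lapply(1:3, function(ci) {
    do.call(rbind, lapply(seq_along(metric_names), function(mi) {
      vals <- acc[, ci, mi]
      pt <- mean(vals)
      # percentile band, extended to cover the mean when the per-repeat
      # distribution is so skewed or discrete that the mean falls outside
      data.frame(class = lev[ci], metric = metric_names[mi], point = pt,
                 ci_lo = min(unname(stats::quantile(vals, 0.025)), pt),
                 ci_hi = max(unname(stats::quantile(vals, 0.975)), pt))
    }))
  }))
  conf <- conf_sum / n_repeats
  new("RiskEvalReport", metrics = met, confusion = conf,
      n_repeats = as.integer(n_repeats), per_drug = as.integer(per_drug),
      seed = as.integer(seed))
}

#' @rdname accessors
#' @export
setMethod("evalMetrics", "RiskEvalReport", function(object) object@metrics)

#' @rdname accessors
#' @export
setMethod("confusionMatrix", "RiskEvalReport", function(object) {
  object@confusion
})

setMethod("show", "RiskEvalReport", function(object) {
  cat("RiskEvalReport:", object@n_repeats, "repeats,", object@per_drug,
      "samples/drug/repeat\n")
  m <- object@metrics
  for (cls in tdpRiskLevels()) {
    sub <- m[m$class == cls, ]
    cat(sprintf("  %-12s", cls))
    cat(paste(sprintf("%s=%.3f (%.3f-%.3f)", sub$metric, sub$point,
                      sub$ci_lo, sub$ci_hi)[1:3], collapse = "  "), "\n")
  }
})
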