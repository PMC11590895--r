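#' Confusion matrix with one-vs-rest counts
#'
#' Tallies actual vs predicted labels over a fixed class list and derives
#' the per-class one-vs-rest counts TP, FP, FN, TN used by all downstream
#' metrics.
#'
#' @param actual,predicted equal-length label vectors over \code{classes}.
#' @param classes class vocabulary (fixes row/column order).
#' @return A \code{ConfusionMatrix}: list(classes, table, counts, n) where
#'   \code{table} is the actual-by-predicted count grid and \code{counts} a
#'   per-class data.frame of TP/FP/FN/TN.
#' @export
confusion <- function(actual, predicted, classes = sort(unique(c(actual, predicted)))) {
  if (!length(actual) || length(actual) != length(predicted))
    stop("shape error: actual and predicted must be non-empty and equal length",
         call. = FALSE)
  unknown <- setdiff(unique(c(actual, predicted)), classes)
  if (length(unknown))
    stop("vocabulary error: label(s) outside the class list: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  tab <- table(factor(actual, classes), factor(predicted, classes))
  n <- length(actual)
  counts <- data.frame(class = classes,
                       tp = diag(tab),
                       fp = colSums(tab) - diag(tab),
                       fn = rowSums(tab) - diag(tab))
  counts$tn <- n - counts$tp - counts$fp - counts$fn
  rownames(counts) <- NULL
  structure(list(classes = classes, table = unclass(tab), counts = counts,
                 n = n), class = "ConfusionMatrix")
}

#' F1 score from precision and sensitivity
#'
#' The harmonic mean \eqn{F1 = 2 \cdot PPV \cdot TPR / (PPV + TPR)}. Scale
#' invariant of degree one: inputs in percent give the F1 in percent.
#'
#' @param ppv positive-predictive value (precision).
#' @param tpr true-positive rate (sensitivity).
#' @return F1 on the scale of the inputs; NA when both inputs are zero.
#' @export
#' @examples
#' f1Score(93.70, 93.49)  # 93.59
f1Score <- function(ppv, tpr) {
  ifelse(ppv + tpr == 0, NA_real_, 2 * ppv * tpr / (ppv + tpr))
}

#' Per-class and overall classification metrics
#'
#' For every class, one-vs-rest accuracy, TPR (sensitivity), TNR
#' (specificity), PPV (precision) and F1, reported in percent. The
#' \code{"Overall"} row is the unweighted macro average across classes;
#' metrics with a zero denominator are undefined (NA), logged, and excluded
#' from the macro average. In the two-class case the TPR of one class
#' equals the TNR of the other and both share one accuracy.
#'
#' @param cm a \code{\link{confusion}} matrix.
#' @return data.frame(class, accuracy, tpr, tnr, ppv, f1) in percent, with
#'   an \code{"Overall"} macro row.
#' @export
classMetrics <- function(cm) {
  ct <- cm$counts
  safe_div <- function(a, b) ifelse(b == 0, NA_real_, a / b)
  acc <- (ct$tp + ct$tn) / cm$n
  tpr <- safe_div(ct$tp, ct$tp + ct$fn)
  tnr <- safe_div(ct$tn, ct$tn + ct$fp)
  ppv <- safe_div(ct$tp, ct$tp + ct$fp)
  f1 <- f1Score(ppv, tpr)
  out <- data.frame(class = ct$class, accuracy = 100 * acc, tpr = 100 * tpr,
                    tnr = 100 * tnr, ppv = 100 * ppv, f1 = 100 * f1)
  if (anyNA(out[-1]))
    message("undefined metric(s) (zero denominator) excluded from the macro average")
  macro <- vapply(out[-1], function(v) mean(v, na.rm = TRUE), numeric(1))
  rbind(out, data.frame(class = "Overall", t(macro)))
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the unique scores, records
#' (FPR, TPR) at each threshold (predict positive when score >= threshold)
#' and integrates the curve by the trapezoid rule. Equals the
#' Mann-Whitney pairwise-concordance probability (ties counted 1/2).
#'
#' @param actual binary label vector.
#' @param scores numeric scores, higher meaning more likely positive.
#' @param positive the positive-class label.
#' @return list(thresholds, tpr, fpr, auc); the curve runs from (0,0) to
#'   (1,1).
#' @export
rocAuc <- function(actual, scores, positive) {
  pos <- actual == positive
  if (!any(pos) || all(pos))
    stop("argument error: both classes must be present", call. = FALSE)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(th) mean(scores[pos] >= th), numeric(1))
  fpr <- vapply(thr, function(th) mean(scores[!pos] >= th), numeric(1))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc)
}

#' Daily behavior time budgets: predicted vs observed
#'
#' Converts per-window class predictions into daily behavior durations by
#' assigning \code{windowS} seconds to each window (windows must be
#' non-overlapping, e.g. produced at overlap 0), and compares them with the
#' durations observed in the annotation tracks. Untagged action time counts
#' toward \code{"others"}: its observed duration is the state-tier coverage
#' minus the tagged action time.
#'
#' @param predictions data.frame(calf_id, start_s, label) of non-overlapping
#'   window predictions.
#' @param tracks list of \linkS4class{AnnotationTrack}s (one per calf).
#' @param windowS window length in seconds.
#' @param tier \code{"action"} or \code{"state"}: tier of the predicted
#'   labels.
#' @return data.frame(calf_id, day, behavior, predicted_s, observed_s).
#' @export
timeBudget <- function(predictions, tracks, windowS = 10, tier = "action") {
  names(tracks) <- vapply(tracks, calfId, character(1))
  p <- predictions[order(predictions$calf_id, predictions$start_s), ]
  for (id in unique(p$calf_id)) {
    s <- p$start_s[p$calf_id == id]
    if (length(s) > 1 && any(diff(s) < windowS - 1e-9))
      stop("aggregation error: prediction windows overlap for calf ", id,
           call. = FALSE)
  }
  p$day <- floor(p$start_s / 86400)
  classes <- if (tier == "action") ACTION_CLASSES else STATE_CLASSES
  out <- list()
  for (id in unique(p$calf_id)) {
    iv <- intervals(tracks[[id]])
    for (day in unique(p$day[p$calf_id == id])) {
      d0 <- day * 86400; d1 <- d0 + 86400
      pd <- p[p$calf_id == id & p$day == day, ]
      clip <- function(rows) sum(pmax(0, pmin(rows$end_s, d1) - pmax(rows$start_s, d0)))
      covered <- clip(iv[iv$tier == "state", ])
      for (b in classes) {
        obs <- if (b == "others")
          covered - clip(iv[iv$tier == "action", ])
        else clip(iv[iv$tier == (if (b %in% STATE_CLASSES) "state" else "action") &
                       iv$behavior == b, ])
        out[[length(out) + 1]] <- data.frame(
          calf_id = id, day = day, behavior = b,
          predicted_s = windowS * sum(pd$label == b), observed_s = obs)
      }
    }
  }
  do.call(rbind, out)
}

#' Daily cough frequency: predicted vs observed counts
#'
#' Cough events are validated as daily counts, not seconds: the number of
#' event windows predicted as coughing per calf-day against the number of
#' annotated cough intervals.
#'
#' @param predictions data.frame(calf_id, t_s, label) of classified event
#'   windows (one row per event window, \code{t_s} the peak time).
#' @param tracks list of \linkS4class{AnnotationTrack}s.
#' @return data.frame(calf_id, day, predicted_n, observed_n).
#' @export
coughFrequency <- function(predictions, tracks) {
  names(tracks) <- vapply(tracks, calfId, character(1))
  out <- list()
  for (id in names(tracks)) {
    iv <- intervals(tracks[[id]])
    ev <- iv[iv$tier == "event" & iv$behavior == "coughing", ]
    pd <- predictions[predictions$calf_id == id, , drop = FALSE]
    days <- sort(unique(c(floor(ev$start_s / 86400),
                          if (nrow(pd)) floor(pd$t_s / 86400) else 0)))
    for (day in days) {
      d0 <- day * 86400; d1 <- d0 + 86400
      out[[length(out) + 1]] <- data.frame(
        calf_id = id, day = day,
        predicted_n = sum(pd$label == "coughing" & pd$t_s >= d0 & pd$t_s < d1),
        observed_n = sum(ev$start_s >= d0 & ev$start_s < d1))
    }
  }
  do.call(rbind, out)
}

#' Pearson product-moment correlation
#'
#' Used to validate predicted against observed daily time budgets.
#'
#' @param x,y equal-length numeric vectors (length >= 3, both nonconstant).
#' @return Correlation coefficient in [-1, 1].
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("argument error: need equal lengths >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined-correlation error: constant input", call. = FALSE)
  stats::cor(x, y)
}

#' Cohen's kappa for inter-observer agreement
#'
#' Chance-corrected agreement \eqn{K = (P_0 - P_c) / (1 - P_c)} between two
#' observers' categorical label sequences, where \eqn{P_0} is the observed
#' agreement fraction and \eqn{P_c} the agreement expected by chance from
#' the product of the observers' marginal frequencies.
#'
#' @param x,y equal-length label sequences, or NULL when \code{table} given.
#' @param table a square contingency table (observer 1 rows, observer 2
#'   columns) instead of sequences.
#' @return list(kappa, p0, pc).
#' @export
#' @examples
#' cohensKappa(table = matrix(c(20, 10, 5, 15), 2))$kappa  # 0.4
cohensKappa <- function(x = NULL, y = NULL, table = NULL) {
  if (is.null(table)) {
    if (length(x) != length(y) || !length(x))
      stop("shape error: sequences must be non-empty and equal length",
           call. = FALSE)
    lev <- sort(unique(c(as.character(x), as.character(y))))
    table <- base::table(factor(x, lev), factor(y, lev))
  }
  table <- as.matrix(table)
  n <- sum(table)
  p0 <- sum(diag(table)) / n
  pc <- sum(rowSums(table) * colSums(table)) / n^2
  if (1 - pc < 1e-12)
    stop("undefined-kappa error: chance agreement is 1 (both observers constant)",
         call. = FALSE)
  list(kappa = (p0 - pc) / (1 - pc), p0 = p0, pc = pc)
}

#' Full evaluation report for one model
#'
#' Bundles the confusion matrix, per-class and macro metrics, and (when
#' probability scores are supplied) one-vs-rest ROC AUC per class.
#'
#' @param actual,predicted label vectors.
#' @param classes class vocabulary.
#' @param probs optional matrix/data.frame of per-class probability columns
#'   named \code{prob_<class>}.
#' @return list(confusion, metrics, auc).
#' @export
evaluationReport <- function(actual, predicted, classes, probs = NULL) {
  cm <- confusion(actual, predicted, classes)
  auc <- NULL
  if (!is.null(probs)) {
    auc <- vapply(classes, function(cl) {
      col <- paste0("prob_", cl)
      if (!col %in% colnames(probs) || all(actual == cl) || !any(actual == cl))
        return(NA_real_)
      rocAuc(ifelse(actual == cl, cl, "rest"), probs[[col]], cl)$auc
    }, numeric(1))
  }
  list(confusion = cm, metrics = classMetrics(cm), auc = auc)
}
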