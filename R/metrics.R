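#' One-vs-rest multiclass metrics, macro averages, confidence intervals, AUC
#'
#' The evaluation suite treats each class in turn as positive against the
#' rest, computes precision, sensitivity (recall), specificity, F1 and
#' per-class accuracy from the one-vs-rest counts, and macro-averages them
#' (unweighted mean over classes — appropriate here because class supports
#' are balanced). "Accuracy" in reports is the overall accuracy
#' `sum(TP) / N`, the quantity the benchmark tables print; the mean of
#' per-class `(TP+TN)/N` values is exposed separately as
#' `macro_class_accuracy` because the two differ (for a 4-class problem at
#' overall accuracy 0.719 the latter is ~0.86).
#'
#' Metrics with a zero denominator (e.g. precision when a class is never
#' predicted) are *undefined* and carried as `NA_real_`, never silently 0;
#' macro averages over an undefined value are `NA` unless `na_rm = TRUE`.
#'
#' @name metrics
NULL

#' Per-class metrics from one-vs-rest counts
#'
#' @param counts a [class_counts()] object.
#' @return a list of class `"class_metrics"`: `precision`, `sensitivity`,
#'   `specificity`, `f1`, `class_accuracy`, `counts`. Undefined (0/0) values
#'   are `NA_real_`.
#' @examples
#' class_metrics(class_counts(172, 59, 78, 691))
#' @export
class_metrics <- function(counts) {
  stopifnot(inherits(counts, "class_counts"))
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  precision   <- frac(counts$tp, counts$tp + counts$fp)
  sensitivity <- frac(counts$tp, counts$tp + counts$fn)
  specificity <- frac(counts$tn, counts$tn + counts$fp)
  f1 <- if (!is.na(precision) && !is.na(sensitivity) &&
            (precision + sensitivity) > 0) {
    2 * precision * sensitivity / (precision + sensitivity)
  } else NA_real_
  n <- counts$tp + counts$fp + counts$fn + counts$tn
  structure(
    list(precision = precision, sensitivity = sensitivity,
         specificity = specificity, f1 = f1,
         class_accuracy = frac(counts$tp + counts$tn, n), counts = counts),
    class = "class_metrics")
}

#' Binomial proportion confidence interval
#'
#' `"wilson"` is the score interval (the Newcombe recommendation for single
#' proportions); `"wald"` is the normal approximation `p +/- z * sqrt(p(1-p)/n)`
#' clipped to `[0, 1]`.
#'
#' @param successes,n counts, `0 <= successes <= n`, `n > 0`.
#' @param method `"wilson"` (default) or `"wald"`.
#' @param level confidence level (default 0.95).
#' @return numeric `c(low, high)`.
#' @examples
#' proportion_ci(172, 250)                     # (0.628, 0.742)
#' proportion_ci(719, 1000, method = "wald")   # (0.691, 0.747)
#' @export
proportion_ci <- function(successes, n, method = c("wilson", "wald"),
                          level = 0.95) {
  method <- match.arg(method)
  if (n <= 0) stop("n must be positive", call. = FALSE)
  if (successes < 0 || successes > n) {
    stop("successes must lie in [0, n]", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- successes / n
  if (method == "wald") {
    hw <- z * sqrt(p * (1 - p) / n)
    ci <- c(p - hw, p + hw)
  } else {
    denom <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / denom
    hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    ci <- c(centre - hw, centre + hw)
  }
  pmin(pmax(ci, 0), 1)
}

#' Macro-average confidence interval
#'
#' The unweighted mean of per-class interval bounds, computed on unrounded
#' bounds (the convention of the benchmark's macro CI columns).
#'
#' @param cis list of `c(low, high)` pairs, one per class.
#' @return numeric `c(low, high)`.
#' @export
macro_ci <- function(cis) {
  m <- do.call(rbind, cis)
  c(mean(m[, 1L]), mean(m[, 2L]))
}

#' Full metric report for one classifier
#'
#' @param counts_by_class list of [class_counts()], one per class, in
#'   registry order (names taken as class labels), or a data.frame with
#'   columns `class, tp, fp, fn, tn`.
#' @param ci_method `"wilson"`, `"wald"`, or `NULL` to skip intervals.
#' @param level confidence level.
#' @param na_rm drop undefined per-class values from macro averages instead
#'   of propagating `NA`.
#' @return object of class `"metric_report"`: `per_class` data.frame
#'   (precision, sensitivity, specificity, f1, class_accuracy and their CIs),
#'   `macro` named list (precision, sensitivity, specificity, f1,
#'   macro_class_accuracy), `overall_accuracy`, `macro_cis`,
#'   `overall_accuracy_ci`, `n`.
#' @examples
#' tbl <- load_fixture("counts16")
#' rx <- tbl[tbl$classifier == "ResNeXt101", ]
#' rep <- metric_report(rx)
#' rep$overall_accuracy          # 0.719
#' @export
metric_report <- function(counts_by_class, ci_method = "wilson", level = 0.95,
                          na_rm = FALSE) {
  if (is.data.frame(counts_by_class)) {
    df <- counts_by_class
    stopifnot(all(c("class", "tp", "fp", "fn", "tn") %in% names(df)))
    counts_by_class <- stats::setNames(
      lapply(seq_len(nrow(df)),
             function(i) class_counts(df$tp[i], df$fp[i], df$fn[i], df$tn[i])),
      df$class)
  }
  cls <- names(counts_by_class)
  if (is.null(cls)) cls <- paste0("class", seq_along(counts_by_class))
  mets <- lapply(counts_by_class, class_metrics)
  n <- counts_by_class[[1L]]$tp + counts_by_class[[1L]]$fp +
    counts_by_class[[1L]]$fn + counts_by_class[[1L]]$tn
  for (cc in counts_by_class) {
    if (cc$tp + cc$fp + cc$fn + cc$tn != n) {
      stop("all classes must share the same total N", call. = FALSE)
    }
  }

  per <- data.frame(
    class = cls,
    precision      = vapply(mets, `[[`, 0, "precision"),
    sensitivity    = vapply(mets, `[[`, 0, "sensitivity"),
    specificity    = vapply(mets, `[[`, 0, "specificity"),
    f1             = vapply(mets, `[[`, 0, "f1"),
    class_accuracy = vapply(mets, `[[`, 0, "class_accuracy"),
    row.names = NULL)

  avg <- function(x) if (na_rm) mean(x, na.rm = TRUE) else mean(x)
  macro <- list(precision = avg(per$precision),
                sensitivity = avg(per$sensitivity),
                specificity = avg(per$specificity),
                f1 = avg(per$f1),
                macro_class_accuracy = avg(per$class_accuracy))
  overall <- sum(vapply(counts_by_class, `[[`, 0L, "tp")) / n

  macro_cis <- NULL
  overall_ci <- NULL
  if (!is.null(ci_method)) {
    ci_of <- function(cc, what) {
      den <- switch(what,
                    precision   = cc$tp + cc$fp,
                    sensitivity = cc$tp + cc$fn,
                    specificity = cc$tn + cc$fp)
      num <- switch(what,
                    precision = cc$tp, sensitivity = cc$tp,
                    specificity = cc$tn)
      if (den == 0) c(NA_real_, NA_real_)
      else proportion_ci(num, den, method = ci_method, level = level)
    }
    for (what in c("precision", "sensitivity", "specificity")) {
      cim <- t(vapply(counts_by_class, ci_of, numeric(2L), what = what))
      per[[paste0(what, "_low")]] <- cim[, 1L]
      per[[paste0(what, "_high")]] <- cim[, 2L]
    }
    macro_cis <- list(
      precision   = macro_ci(Map(c, per$precision_low, per$precision_high)),
      sensitivity = macro_ci(Map(c, per$sensitivity_low, per$sensitivity_high)),
      specificity = macro_ci(Map(c, per$specificity_low, per$specificity_high)))
    overall_ci <- proportion_ci(round(overall * n), n, method = ci_method,
                                level = level)
  }

  structure(
    list(per_class = per, macro = macro, overall_accuracy = overall,
         macro_cis = macro_cis, overall_accuracy_ci = overall_ci,
         n = n, ci_method = ci_method, level = level),
    class = "metric_report")
}

#' @export
print.metric_report <- function(x, digits = 3L, ...) {
  cat(sprintf("<metric_report> N=%d, overall accuracy %.3f\n",
              x$n, x$overall_accuracy))
  show <- x$per_class
  num <- vapply(show, is.numeric, TRUE)
  show[num] <- lapply(show[num], round, digits)
  print(show, row.names = FALSE)
  cat(sprintf("macro: precision %.3f, sensitivity %.3f, specificity %.3f, f1 %.3f\n",
              x$macro$precision, x$macro$sensitivity, x$macro$specificity,
              x$macro$f1))
  invisible(x)
}

#' Metric report straight from truth and predicted labels
#'
#' Convenience wrapper: builds the confusion matrix, collapses each class
#' one-vs-rest, and calls [metric_report()].
#'
#' @param truth,pred label vectors (names or 1-based indices).
#' @param classes class registry or label vector.
#' @inheritParams metric_report
#' @return a [metric_report()].
#' @export
evaluate_predictions <- function(truth, pred, classes, ci_method = "wilson",
                                 level = 0.95, na_rm = FALSE) {
  cm <- confusion(truth, pred, classes)
  counts <- stats::setNames(
    lapply(seq_len(nrow(cm)), function(i) ovr_counts(cm, i)), rownames(cm))
  metric_report(counts, ci_method = ci_method, level = level, na_rm = na_rm)
}

# ---- one-vs-rest ROC AUC ---------------------------------------------------

#' One-vs-rest ROC AUC for one class
#'
#' The AUC is computed as the Mann-Whitney statistic on the positive-class
#' probability column (mid-ranks, so ties count 1/2), which equals the area
#' under the empirical ROC curve by trapezoidal integration. Scores are used
#' as-is, without renormalization.
#'
#' @param probs `N x C` probability matrix of one classifier.
#' @param truth label vector (names or 1-based indices).
#' @param class_index 1-based class position or label.
#' @param classes registry; defaults to `colnames(probs)`.
#' @return AUC in `[0, 1]`, or `NA_real_` when the class has no positive or
#'   no negative items.
#' @examples
#' ovr_roc_auc(cbind(a = c(.9, .8, .4, .3), b = c(.1, .2, .6, .7)),
#'             c("a", "b", "a", "b"), "a")
#' @export
ovr_roc_auc <- function(probs, truth, class_index, classes = colnames(probs)) {
  if (!inherits(classes, "class_registry")) classes <- class_registry(classes)
  t_idx <- encode_labels(truth, classes)
  if (is.character(class_index)) {
    class_index <- match(class_index, as.character(classes))
  }
  scores <- probs[, class_index]
  pos <- t_idx == class_index
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Macro-averaged one-vs-rest AUC
#'
#' @inheritParams ovr_roc_auc
#' @param na_rm drop classes with undefined AUC from the mean.
#' @return list with `per_class` (named numeric) and `macro` (their
#'   unweighted mean).
#' @export
macro_auc <- function(probs, truth, classes = colnames(probs), na_rm = FALSE) {
  if (!inherits(classes, "class_registry")) classes <- class_registry(classes)
  per <- vapply(seq_along(classes),
                function(i) ovr_roc_auc(probs, truth, i, classes), 0)
  names(per) <- as.character(classes)
  list(per_class = per, macro = mean(per, na.rm = na_rm))
}

#' One-vs-rest ROC curve points
#'
#' Thresholds are swept over the unique scores; returns the (FPR, TPR)
#' staircase whose trapezoidal area equals [ovr_roc_auc()].
#'
#' @inheritParams ovr_roc_auc
#' @return data.frame with columns `threshold`, `fpr`, `tpr`.
#' @export
ovr_roc_curve <- function(probs, truth, class_index, classes = colnames(probs)) {
  if (!inherits(classes, "class_registry")) classes <- class_registry(classes)
  t_idx <- encode_labels(truth, classes)
  if (is.character(class_index)) {
    class_index <- match(class_index, as.character(classes))
  }
  scores <- probs[, class_index]
  pos <- t_idx == class_index
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), 0)
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), 0)
  data.frame(threshold = thr, fpr = fpr, tpr = tpr)
}

# ---- report writers --------------------------------------------------------

#' Write a metric report to CSV or JSON
#'
#' CSV mirrors the benchmark-table layout (one row per class plus a macro
#' row; point estimates with CI bounds); numbers are printed at 3 decimal
#' places in CSV but full precision in JSON.
#'
#' @param report a [metric_report()].
#' @param path output path; format chosen by extension (`.json` vs other).
#' @return `path`, invisibly.
#' @export
write_metric_report <- function(report, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    return(invisible(path))
  }
  per <- report$per_class
  macro_row <- data.frame(class = "macro",
                          precision = report$macro$precision,
                          sensitivity = report$macro$sensitivity,
                          specificity = report$macro$specificity,
                          f1 = report$macro$f1,
                          class_accuracy = report$macro$macro_class_accuracy)
  for (nm in setdiff(names(per), names(macro_row))) {
    macro_row[[nm]] <- if (nm %in% paste0(c("precision", "sensitivity", "specificity"),
                                          rep(c("_low", "_high"), each = 3))) {
      what <- sub("_(low|high)$", "", nm)
      bound <- if (grepl("_low$", nm)) 1L else 2L
      if (!is.null(report$macro_cis)) report$macro_cis[[what]][bound] else NA_real_
    } else NA_real_
  }
  out <- rbind(per, macro_row[, names(per)])
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], round, 3L)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
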