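# Multiclass evaluation: confusion matrix, one-vs-rest reduction, the
# six-metric battery (accuracy, sensitivity, specificity, precision, F1,
# Matthews correlation), macro averages, ROC and precision-recall curves
# with trapezoidal areas.

#' Confusion matrix
#'
#' `counts[i, j]` is the number of items with true class `i` predicted as
#' class `j`.
#'
#' @param true_labels,predicted_labels equal-length label vectors, drawn from
#'   `class_names`.
#' @param class_names class symbols fixing row/column order.
#' @return integer matrix of class `afw_confusion` with dimnames.
#' @export
confusion_matrix <- function(true_labels, predicted_labels, class_names) {
  if (length(true_labels) != length(predicted_labels)) {
    stop("label sequences must have equal length")
  }
  bad <- setdiff(unique(c(true_labels, predicted_labels)), class_names)
  if (length(bad)) {
    stop("labels outside class_names: ", paste(bad, collapse = ", "))
  }
  tf <- factor(true_labels, levels = class_names)
  pf <- factor(predicted_labels, levels = class_names)
  counts <- table(true = tf, predicted = pf)
  m <- matrix(as.integer(counts), nrow = length(class_names),
              dimnames = list(true = class_names, predicted = class_names))
  structure(m, class = c("afw_confusion", "matrix", "array"))
}

#' One-vs-rest binary counts for one class
#'
#' @param cm an [confusion_matrix()].
#' @param class_index 1-based class index (or class name).
#' @return list with `Tp`, `Fn`, `Fp`, `Tn`.
#' @export
one_vs_rest_counts <- function(cm, class_index) {
  if (is.character(class_index)) {
    class_index <- match(class_index, rownames(cm))
  }
  k <- nrow(cm)
  if (is.na(class_index) || class_index < 1L || class_index > k) {
    stop("class_index out of range")
  }
  tp <- cm[class_index, class_index]
  fn <- sum(cm[class_index, ]) - tp
  fp <- sum(cm[, class_index]) - tp
  tn <- sum(cm) - tp - fn - fp
  list(Tp = as.double(tp), Fn = as.double(fn), Fp = as.double(fp),
       Tn = as.double(tn))
}

#' Six-metric record from binary counts
#'
#' Acc = (Tp+Tn)/N; Se = Tp/(Tp+Fn); Sp = Tn/(Tn+Fp); Pre = Tp/(Tp+Fp);
#' F1 = 2*Se*Pre/(Se+Pre); MCC = (Tp*Tn - Fp*Fn) /
#' sqrt((Tp+Fp)(Tp+Fn)(Tn+Fp)(Tn+Fn)). A metric whose denominator is zero is
#' reported as 0 and named in the `degenerate` field.
#'
#' @param c list with `Tp`, `Fn`, `Fp`, `Tn` (see [one_vs_rest_counts()]).
#' @return list with `acc`, `se`, `sp`, `pre`, `f1`, `mcc` and `degenerate`
#'   (character vector of zero-denominator metrics).
#' @export
class_metrics <- function(c) {
  tp <- as.double(c$Tp); fn <- as.double(c$Fn)
  fp <- as.double(c$Fp); tn <- as.double(c$Tn)
  total <- tp + fn + fp + tn
  if (total <= 0) stop("all-zero counts")
  degenerate <- character(0)
  safe_div <- function(num, den, name) {
    if (den == 0) {
      degenerate <<- c(degenerate, name)
      0
    } else num / den
  }
  se <- safe_div(tp, tp + fn, "se")
  sp <- safe_div(tn, tn + fp, "sp")
  pre <- safe_div(tp, tp + fp, "pre")
  f1 <- safe_div(2 * se * pre, se + pre, "f1")
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- safe_div(tp * tn - fp * fn, mcc_den, "mcc")
  list(acc = (tp + tn) / total, se = se, sp = sp, pre = pre, f1 = f1,
       mcc = mcc, degenerate = degenerate)
}

#' Macro (unweighted arithmetic) average of per-class metric records
#'
#' @param per_class_records list of [class_metrics()] records.
#' @return list with the averaged `acc`, `se`, `sp`, `pre`, `f1`, `mcc`.
#' @export
macro_average <- function(per_class_records) {
  if (length(per_class_records) < 1L) stop("need at least one class record")
  keys <- c("acc", "se", "sp", "pre", "f1", "mcc")
  out <- lapply(keys, function(k) {
    mean(vapply(per_class_records, function(r) r[[k]], numeric(1)))
  })
  names(out) <- keys
  out
}

check_binary_truth <- function(truth) {
  truth <- as.integer(truth)
  if (!all(truth %in% c(0L, 1L))) stop("truth must be binary (0/1 or logical)")
  if (length(unique(truth)) < 2L) {
    stop("truth must contain both classes")
  }
  truth
}

# Grouped threshold sweep: descending unique scores, cumulative counts with
# score ties grouped.
threshold_sweep <- function(scores, truth) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- truth[ord]
  grp_last <- which(diff(s) != 0)
  grp_last <- c(grp_last, length(s))
  cum_tp <- cumsum(y)[grp_last]
  cum_fp <- cumsum(1 - y)[grp_last]
  list(threshold = s[grp_last], tp = cum_tp, fp = cum_fp,
       P = sum(y), N = sum(1 - y))
}

#' ROC curve and area for one class
#'
#' Sweeps every distinct score threshold (ties grouped), anchored at
#' (0, 0) and (1, 1); the area is trapezoidal over false positive rate.
#'
#' @param scores_for_class scores in `[0, 1]`, higher = more positive.
#' @param binary_truth logical or 0/1 vector with both values present.
#' @return list with `points` (data.frame threshold, fpr, tpr) and `auc`.
#' @export
roc_points_and_auc <- function(scores_for_class, binary_truth) {
  truth <- check_binary_truth(binary_truth)
  sw <- threshold_sweep(scores_for_class, truth)
  fpr <- c(0, sw$fp / sw$N)
  tpr <- c(0, sw$tp / sw$P)
  points <- data.frame(threshold = c(Inf, sw$threshold), fpr = fpr, tpr = tpr)
  list(points = points, auc = trapz_area(fpr, tpr))
}

#' Precision-recall curve, area, and recall at a precision floor
#'
#' Sweeps every distinct score threshold (ties grouped). The area is
#' trapezoidal over recall, anchored at recall 0 with the first group's
#' precision. `recall_at_precision(p)` is the maximal recall over thresholds
#' whose precision is at least `p` (0 when none qualifies).
#'
#' @param scores_for_class scores in `[0, 1]`.
#' @param binary_truth logical or 0/1 vector; at least one positive required.
#' @return list with `points` (threshold, precision, recall), `auc`, and
#'   `recall_at_precision` (a function of the precision floor).
#' @export
pr_points_and_auc <- function(scores_for_class, binary_truth) {
  truth <- as.integer(binary_truth)
  if (sum(truth) == 0L) stop("truth contains no positives")
  sw <- threshold_sweep(scores_for_class, truth)
  precision <- sw$tp / (sw$tp + sw$fp)
  recall <- sw$tp / sw$P
  points <- data.frame(threshold = sw$threshold, precision = precision,
                       recall = recall)
  auc <- trapz_area(c(0, recall), c(precision[1L], precision))
  recall_at <- function(p) {
    ok <- precision >= p
    if (!any(ok)) 0 else max(recall[ok])
  }
  list(points = points, auc = auc, recall_at_precision = recall_at)
}

#' Full evaluation report
#'
#' Builds the confusion matrix, per-class six-metric records (one-vs-rest),
#' macro averages, and — when a score matrix is supplied — per-class ROC and
#' PR areas plus recall at precision 0.9. Note: per-class accuracy is
#' one-vs-rest accuracy (Tp+Tn)/N; reports that list per-class accuracy
#' equal to sensitivity are quoting recall, which is the `se` field here.
#'
#' @param true_labels,predicted_labels label vectors.
#' @param scores optional n x K score matrix (columns ordered as
#'   `class_names`).
#' @param class_names class symbols.
#' @return object of class `metrics_report`.
#' @export
metrics_report <- function(true_labels, predicted_labels, scores = NULL,
                           class_names = sort(unique(true_labels))) {
  cm <- confusion_matrix(true_labels, predicted_labels, class_names)
  per_class <- lapply(seq_along(class_names), function(k) {
    class_metrics(one_vs_rest_counts(cm, k))
  })
  names(per_class) <- class_names
  report <- list(confusion = cm, per_class = per_class,
                 macro = macro_average(per_class),
                 class_names = class_names)
  if (!is.null(scores)) {
    aucs <- lapply(seq_along(class_names), function(k) {
      truth <- as.integer(true_labels == class_names[k])
      roc <- tryCatch(roc_points_and_auc(scores[, k], truth),
                      error = function(e) NULL)
      pr <- tryCatch(pr_points_and_auc(scores[, k], truth),
                     error = function(e) NULL)
      list(auc_roc = if (is.null(roc)) NA_real_ else roc$auc,
           auc_pr = if (is.null(pr)) NA_real_ else pr$auc,
           recall_at_p90 = if (is.null(pr)) NA_real_ else
             pr$recall_at_precision(0.9))
    })
    names(aucs) <- class_names
    report$curves <- aucs
  }
  structure(report, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat("Confusion matrix (rows = true, columns = predicted):\n")
  print(unclass(x$confusion))
  df <- as.data.frame(x)
  cat("\nPer-class metrics (one-vs-rest):\n")
  print(format(df, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  keys <- c("acc", "se", "sp", "pre", "f1", "mcc")
  rows <- lapply(c(x$class_names, "macro"), function(cls) {
    rec <- if (cls == "macro") x$macro else x$per_class[[cls]]
    row <- as.data.frame(rec[keys])
    row$class <- cls
    if (!is.null(x$curves) && cls != "macro") {
      row$auc_roc <- x$curves[[cls]]$auc_roc
      row$auc_pr <- x$curves[[cls]]$auc_pr
    } else if (!is.null(x$curves)) {
      row$auc_roc <- mean(vapply(x$curves, `[[`, numeric(1), "auc_roc"))
      row$auc_pr <- mean(vapply(x$curves, `[[`, numeric(1), "auc_pr"))
    }
    row
  })
  df <- do.call(rbind, rows)
  df[, c("class", setdiff(names(df), "class"))]
}
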