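# Leave-one-subject-out discrimination of individuals from a single
# biomarker M-psi value, with confusion-matrix metrics.

#' Leave-one-subject-out median-closeness discrimination
#'
#' For each subject, the medians of the biomarker value in both groups are
#' recomputed with that subject left out, and the subject is assigned to the
#' group whose median is closer. The rule is deliberately plain (no fitted
#' classifier) so that the biomarker's diagnostic value is read off
#' directly; chance level is 0.5. Exact distance ties are assigned to the
#' non-target group (conservative; configurable).
#'
#' @param values numeric biomarker values (one per subject).
#' @param groups group label per subject.
#' @param contrast length-2 character: (target group, other group). Only
#'   subjects of these two groups enter; both must have >= 2 members.
#' @param tie_break group receiving exact distance ties: `"other"`
#'   (default) or `"target"`.
#' @return An object of class `loso_result`: list with `contrast`,
#'   `predictions` (data frame: value, group, predicted, correct),
#'   `confusion` (2x2 counts, predicted x actual), `accuracy`,
#'   `sensitivity`, `specificity`.
#' @export
loso_discriminate <- function(values, groups, contrast,
                              tie_break = c("other", "target")) {
  tie_break <- match.arg(tie_break)
  stopifnot(length(contrast) == 2L, length(values) == length(groups))
  keep <- groups %in% contrast
  values <- values[keep]; groups <- as.character(groups[keep])
  target <- contrast[1L]; other <- contrast[2L]
  for (g in contrast) {
    if (sum(groups == g) < 2L)
      stop("group '", g, "' has fewer than 2 subjects")
  }
  n <- length(values)
  pred <- character(n)
  for (i in seq_len(n)) {
    med_t <- stats::median(values[-i][groups[-i] == target])
    med_o <- stats::median(values[-i][groups[-i] == other])
    dt <- abs(values[i] - med_t); do_ <- abs(values[i] - med_o)
    pred[i] <- if (dt < do_) target
      else if (do_ < dt) other
      else if (tie_break == "other") other else target
  }
  metrics <- confusion_metrics(pred, groups, target)
  structure(list(contrast = contrast,
                 predictions = data.frame(value = values, group = groups,
                                          predicted = pred,
                                          correct = pred == groups,
                                          stringsAsFactors = FALSE),
                 confusion = metrics$confusion,
                 accuracy = metrics$accuracy,
                 sensitivity = metrics$sensitivity,
                 specificity = metrics$specificity),
            class = "loso_result")
}

#' @export
print.loso_result <- function(x, ...) {
  cat("<loso_result> ", x$contrast[1L], " vs ", x$contrast[2L], " (n = ",
      nrow(x$predictions), ")\n", sep = "")
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.2f", v)
  cat("  accuracy ", fmt(x$accuracy), ", sensitivity ", fmt(x$sensitivity),
      ", specificity ", fmt(x$specificity), "\n", sep = "")
  print(x$confusion)
  invisible(x)
}

#' Confusion-matrix metrics for a two-group discrimination
#'
#' Accuracy is the overall fraction correct; sensitivity the fraction of
#' actual target-group subjects predicted as target; specificity the
#' fraction of actual non-target subjects predicted as non-target. A metric
#' whose denominator class is empty is reported as `NA`, not 0.
#'
#' @param predicted,actual label vectors (two classes).
#' @param target the target-group label.
#' @return list with `confusion` (2x2 counts, predicted x actual),
#'   `accuracy`, `sensitivity`, `specificity`.
#' @export
confusion_metrics <- function(predicted, actual, target) {
  stopifnot(length(predicted) == length(actual))
  is_t_pred <- predicted == target
  is_t_act <- actual == target
  tp <- sum(is_t_pred & is_t_act); fn <- sum(!is_t_pred & is_t_act)
  fp <- sum(is_t_pred & !is_t_act); tn <- sum(!is_t_pred & !is_t_act)
  confusion <- matrix(c(tp, fn, fp, tn), 2L, 2L,
                      dimnames = list(predicted = c(target, "other"),
                                      actual = c(target, "other")))
  list(confusion = confusion,
       accuracy = (tp + tn) / length(actual),
       sensitivity = if (tp + fn > 0L) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0L) tn / (tn + fp) else NA_real_)
}

#' Normalised confusion matrix
#'
#' Column-normalised (per actual class) confusion matrix, the layout used to
#' display two-class discrimination results.
#'
#' @param x a `loso_result`.
#' @return 2x2 matrix of fractions per actual class.
#' @export
normalized_confusion <- function(x) {
  stopifnot(inherits(x, "loso_result"))
  sweep(x$confusion, 2L, pmax(colSums(x$confusion), 1L), "/")
}
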