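#' Confusion matrix
#'
#' Cross-tabulates 0-based true and predicted class indices: `counts[i, j]`
#' is the number of segments of true class `i - 1` predicted as `j - 1`.
#'
#' @param true_labels,predicted_labels equal-length integer vectors of
#'   0-based classes.
#' @param n_classes number of classes.
#' @return `n_classes x n_classes` integer matrix of class
#'   `confusion_matrix` (rows = true, columns = predicted).
#' @examples
#' confusion_matrix(c(0, 0, 1, 1), c(0, 1, 1, 1), 2)
#' @export
confusion_matrix <- function(true_labels, predicted_labels, n_classes) {
  if (length(true_labels) != length(predicted_labels))
    stopf("label vectors differ in length (%d vs %d)",
          length(true_labels), length(predicted_labels))
  labs <- c(true_labels, predicted_labels)
  if (length(labs) && (any(labs < 0) || any(labs >= n_classes)))
    stopf("labels must lie in [0, %d)", n_classes)
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(true_labels))
    cm[true_labels[i] + 1L, predicted_labels[i] + 1L] <-
      cm[true_labels[i] + 1L, predicted_labels[i] + 1L] + 1L
  dimnames(cm) <- list(true = 0:(n_classes - 1), predicted = 0:(n_classes - 1))
  structure(cm, class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> rows = true class, columns = predicted\n")
  print(unclass(x))
  invisible(x)
}

#' Accuracy, precision, recall and F1 from a confusion matrix
#'
#' Accuracy is the trace over the total. Each class is scored one-vs-rest:
#' precision `TP / (TP + FP)`, recall `TP / (TP + FN)`, and
#' `F1 = 2PR / (P + R)`; a class never predicted (or with `P + R = 0`) gets
#' 0 rather than NaN. Macro metrics are unweighted class means.
#'
#' @param cm a [confusion_matrix()].
#' @return a `metrics_report`: `accuracy`, per-class `precision`, `recall`,
#'   `f1`, and `macro_precision`, `macro_recall`, `macro_f1`.
#' @export
metrics_from_confusion <- function(cm) {
  m <- unclass(cm)
  total <- sum(m)
  if (total == 0) stopf("empty confusion matrix")
  K <- nrow(m)
  tp <- diag(m)
  fp <- colSums(m) - tp
  fn <- rowSums(m) - tp
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  structure(list(accuracy = sum(tp) / total,
                 precision = unname(precision), recall = unname(recall),
                 f1 = unname(f1),
                 macro_precision = mean(precision), macro_recall = mean(recall),
                 macro_f1 = mean(f1), n = total),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n = %d\n  accuracy %.4f\n", x$n, x$accuracy))
  cat(sprintf("  macro P %.4f  R %.4f  F1 %.4f\n",
              x$macro_precision, x$macro_recall, x$macro_f1))
  per <- rbind(precision = x$precision, recall = x$recall, f1 = x$f1)
  colnames(per) <- paste0("class", seq_len(ncol(per)) - 1)
  print(round(per, 4))
  invisible(x)
}

#' Compare two sets of accuracies with a t-test
#'
#' Student's two-sample t-test with pooled variance (default) or a paired
#' t-test, two-tailed, for comparing per-subject or per-fold accuracies of
#' two model variants.
#'
#' @param accs_a,accs_b numeric accuracy vectors (length >= 2; equal lengths
#'   when `paired`).
#' @param paired use the paired test.
#' @return list with `t_value`, `p_value`, `df`.
#' @export
compare_models <- function(accs_a, accs_b, paired = FALSE) {
  stopifnot(length(accs_a) >= 2, length(accs_b) >= 2)
  if (paired && length(accs_a) != length(accs_b))
    stopf("paired comparison needs equal-length vectors")
  tiny <- 1e-20
  degenerate <- if (paired) stats::var(accs_a - accs_b) < tiny
                else stats::var(accs_a) < tiny && stats::var(accs_b) < tiny
  if (degenerate) {
    if (isTRUE(all.equal(mean(accs_a), mean(accs_b))))
      return(list(t_value = 0, p_value = 1,
                  df = if (paired) length(accs_a) - 1
                       else length(accs_a) + length(accs_b) - 2))
    stopf("degenerate comparison: zero variance with unequal means")
  }
  tt <- stats::t.test(accs_a, accs_b, paired = paired, var.equal = TRUE)
  list(t_value = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter))
}

#' Ablation report across model variants
#'
#' Collates cross-validation reports of several variants on the same task
#' into a summary table (mean accuracy, variance, macro precision/recall/F1
#' per variant) and a pairwise t-test grid over fold accuracies.
#'
#' @param cv_reports list of `sttcnn_cv` objects sharing a task.
#' @param paired use paired t-tests (folds share the partition when all
#'   reports used the same fold assignment).
#' @return an `ablation_report`: list with data frames `summary` and
#'   `comparisons`.
#' @export
ablation_report <- function(cv_reports, paired = FALSE) {
  stopifnot(length(cv_reports) >= 1,
            all(vapply(cv_reports, inherits, TRUE, "sttcnn_cv")))
  tasks <- unique(vapply(cv_reports, function(r) r$task, ""))
  if (length(tasks) != 1)
    stopf("cross-validation reports mix tasks: %s", paste(tasks, collapse = ", "))
  summary <- do.call(rbind, lapply(cv_reports, function(r) data.frame(
    variant = r$variant, k = r$k,
    mean_accuracy = r$mean_accuracy, variance = r$variance,
    macro_precision = r$metrics$macro_precision,
    macro_recall = r$metrics$macro_recall,
    macro_f1 = r$metrics$macro_f1,
    stringsAsFactors = FALSE)))
  comparisons <- NULL
  if (length(cv_reports) >= 2) {
    pairs <- utils::combn(length(cv_reports), 2)
    comparisons <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      a <- cv_reports[[pairs[1, j]]]; b <- cv_reports[[pairs[2, j]]]
      ct <- tryCatch(compare_models(a$accuracies, b$accuracies, paired = paired),
                     error = function(e) list(t_value = NA_real_,
                                              p_value = NA_real_, df = NA_real_))
      data.frame(variant_a = a$variant, variant_b = b$variant,
                 t_value = ct$t_value, p_value = ct$p_value, df = ct$df,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(task = tasks, summary = summary, comparisons = comparisons),
            class = "ablation_report")
}

#' @export
print.ablation_report <- function(x, digits = 4, ...) {
  cat(sprintf("<ablation_report> task '%s'\n\nVariant summary:\n", x$task))
  s <- x$summary
  s[-1] <- lapply(s[-1], round, digits = digits)
  print(s, row.names = FALSE)
  if (!is.null(x$comparisons)) {
    cat("\nPairwise t-tests on fold accuracies:\n")
    cmp <- x$comparisons
    cmp[3:5] <- lapply(cmp[3:5], round, digits = digits)
    print(cmp, row.names = FALSE)
  }
  invisible(x)
}

#' Write an ablation report as delimited tables
#'
#' Writes `<stem>_summary.tsv` and (when present) `<stem>_comparisons.tsv`.
#'
#' @param x an [ablation_report()].
#' @param stem output path stem.
#' @return paths written, invisibly.
#' @export
write_ablation_report <- function(x, stem) {
  stopifnot(inherits(x, "ablation_report"))
  paths <- character()
  p1 <- paste0(stem, "_summary.tsv")
  utils::write.table(x$summary, p1, sep = "\t", row.names = FALSE, quote = FALSE)
  paths <- p1
  if (!is.null(x$comparisons)) {
    p2 <- paste0(stem, "_comparisons.tsv")
    utils::write.table(x$comparisons, p2, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <- c(paths, p2)
  }
  invisible(paths)
}
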