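#' Confusion matrix
#'
#' Cross-tabulates actual (rows) against predicted (columns) labels over a
#' fixed class set.
#'
#' @param actual,predicted Equal-length label vectors.
#' @param class_labels Class set; default the sorted union of both vectors.
#' @return A `k x k` integer matrix of class `confusion_matrix` with
#'   dimnames `actual` x `predicted`.
#' @export
#' @examples
#' confusion(c(0, 0, 1, 1), c(0, 1, 1, 1))
confusion <- function(actual, predicted, class_labels = NULL) {
  if (length(actual) != length(predicted)) {
    stop_shape("`actual` and `predicted` must have equal length.")
  }
  if (length(actual) == 0) stop_shape("Cannot build a confusion matrix from empty inputs.")
  class_labels <- class_labels %||% sort(unique(c(actual, predicted)))
  bad <- setdiff(unique(c(actual, predicted)), class_labels)
  if (length(bad) > 0) {
    stop_label(sprintf("Label(s) outside the class set: %s",
                       paste(bad, collapse = ", ")))
  }
  counts <- table(factor(actual, levels = class_labels),
                  factor(predicted, levels = class_labels))
  out <- matrix(as.integer(counts), nrow = length(class_labels),
                dimnames = list(actual = as.character(class_labels),
                                predicted = as.character(class_labels)))
  class(out) <- c("confusion_matrix", class(out))
  out
}

#' Binary classification metrics from confusion counts
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, precision
#' `TP/(TP+FP)`, accuracy `(TP+TN)/total`, F-score
#' `2*prec*sens/(prec+sens)` and Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. A metric whose
#' denominator is zero is reported as 0 and named in the `flags` attribute.
#'
#' @param tp,tn,fp,fn Non-negative confusion counts, total > 0.
#' @return A one-row tibble with the six metrics; attribute `flags` lists
#'   metrics that had zero denominators.
#' @export
#' @examples
#' binary_metrics(tp = 50, tn = 40, fp = 5, fn = 5)
binary_metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0)) abort("Counts must be non-negative.",
                             class = "seizecca_error_value")
  total <- sum(counts)
  if (total == 0) abort("Total count must be positive.", class = "seizecca_error_value")
  flags <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) {
      flags <<- c(flags, name)
      0
    } else num / den
  }
  sens <- safe(tp, tp + fn, "sensitivity")
  spec <- safe(tn, tn + fp, "specificity")
  prec <- safe(tp, tp + fp, "precision")
  acc <- (tp + tn) / total
  f1 <- safe(2 * prec * sens, prec + sens, "f_score")
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- safe(tp * tn - fp * fn, mcc_den, "mcc")
  out <- tibble::tibble(sensitivity = sens, specificity = spec,
                        precision = prec, accuracy = acc,
                        f_score = f1, mcc = mcc)
  attr(out, "flags") <- unique(flags)
  out
}

#' Per-class and macro-averaged metrics from a confusion matrix
#'
#' Computes one-vs-rest sensitivity, specificity, precision, F-score and MCC
#' per class, their unweighted macro means, and the overall accuracy
#' (trace / total).
#'
#' @param cm A [confusion()] matrix (`k >= 2`).
#' @return A list of class `metrics_report`: `per_class` tibble (one row per
#'   class), `averaged` one-row tibble of macro means, `accuracy`,
#'   `confusion`. Optionally carries `auc` when attached by [roc_curve()]
#'   consumers.
#' @export
multiclass_metrics <- function(cm) {
  if (!inherits(cm, "confusion_matrix")) cm <- confusion_as_matrix(cm)
  k <- nrow(cm)
  total <- sum(cm)
  if (k < 2 || total == 0) abort("Confusion matrix must be at least 2x2 and non-empty.",
                                 class = "seizecca_error_value")
  labels <- rownames(cm)
  per <- purrr::map(seq_len(k), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- total - tp - fn - fp
    row <- binary_metrics(tp, tn, fp, fn)
    dplyr::bind_cols(tibble::tibble(class = labels[i]), row)
  })
  per_class <- dplyr::bind_rows(per)
  averaged <- dplyr::summarise(per_class, dplyr::across(
    c("sensitivity", "specificity", "precision", "f_score", "mcc"), mean))
  structure(
    list(per_class = per_class,
         averaged = averaged,
         accuracy = sum(diag(cm)) / total,
         confusion = cm),
    class = "metrics_report"
  )
}

confusion_as_matrix <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop_shape("Confusion matrix must be square.")
  if (is.null(rownames(cm))) {
    rownames(cm) <- colnames(cm) <- as.character(seq_len(nrow(cm)) - 1L)
  }
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Accuracy: %.4f\n", x$accuracy))
  cat("Macro-averaged one-vs-rest metrics:\n")
  print(x$averaged)
  invisible(x)
}

#' One-vs-rest ROC curves and AUC
#'
#' Sweeps thresholds over the distinct scores of each class (descending),
#' yielding (FPR, TPR) points, and integrates the area by the trapezoid
#' rule; tied scores are grouped so ties receive half credit, making the AUC
#' identical to the normalised Mann-Whitney U statistic. The macro AUC is
#' the unweighted mean over classes.
#'
#' @param scores Numeric matrix or data frame of per-class scores (higher
#'   means more likely that class), one column per class; columns named
#'   `.score_<class>` or `<class>`.
#' @param actual Length-`n` vector of true labels.
#' @return A tibble of class `roc_curve` with columns `class`, `threshold`,
#'   `fpr`, `tpr`; attributes `auc` (tibble `class`, `auc`) and `macro_auc`.
#' @export
roc_curve <- function(scores, actual) {
  scores <- as.matrix(scores)
  if (nrow(scores) != length(actual)) {
    stop_shape("`scores` rows must match the length of `actual`.")
  }
  if (length(unique(actual)) < 2) {
    abort("ROC analysis needs at least two classes.", class = "seizecca_error_value")
  }
  cls_names <- sub("^\\.score_", "", colnames(scores) %||% as.character(sort(unique(actual))))
  curves <- purrr::map(seq_len(ncol(scores)), function(j) {
    cls <- cls_names[j]
    pos <- actual == cls
    n_pos <- sum(pos)
    n_neg <- sum(!pos)
    if (n_pos == 0 || n_neg == 0) return(NULL)
    s <- scores[, j]
    ord <- order(s, decreasing = TRUE)
    s <- s[ord]
    pos <- pos[ord]
    groups <- cumsum(!duplicated(s))
    tp <- cumsum(pos)
    fp <- cumsum(!pos)
    last <- !duplicated(groups, fromLast = TRUE)
    tibble::tibble(
      class = cls,
      threshold = c(Inf, s[last]),
      tpr = c(0, tp[last] / n_pos),
      fpr = c(0, fp[last] / n_neg)
    )
  })
  curves <- dplyr::bind_rows(curves)
  aucs <- curves |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(auc = sum(diff(.data$fpr) * (head(.data$tpr, -1) + tail(.data$tpr, -1)) / 2))
  out <- curves
  class(out) <- c("roc_curve", class(out))
  attr(out, "auc") <- aucs
  attr(out, "macro_auc") <- mean(aucs$auc)
  out
}

#' Stratified k-fold cross-validation of a train/predict pipeline
#'
#' Splits the rows into stratified folds (per-class fold sizes differ by at
#' most one), fits the pipeline on each training portion and evaluates on
#' the held-out fold, so every leakage-prone step (normalization, feature
#' selection, tuning) must live inside `fit`. Returns per-fold metric
#' reports and a pooled report from the summed confusion matrix; when the
#' predictions carry `.score_*` columns a pooled one-vs-rest macro AUC is
#' attached.
#'
#' @param data Feature table with a label column.
#' @param fit Function `(train_data) -> model`.
#' @param predict_fn Function `(model, test_data) -> tibble` with at least a
#'   `.pred_class` column (and optionally `.score_*` columns).
#' @param k Number of folds (default 10). Every class needs at least `k`
#'   members.
#' @param seed Seed for the fold assignment.
#' @param label_column Name of the label column.
#' @return A list of class `cv_result`: `fold_reports`, `pooled` (a
#'   [multiclass_metrics()] report), `pooled_confusion`, `fold_assignments`,
#'   `predictions` (tibble with row, fold, actual, predicted, scores),
#'   `macro_auc` (or `NA`), `roc`.
#' @export
kfold_evaluate <- function(data, fit, predict_fn, k = 10, seed = 1,
                           label_column = "y") {
  parts <- split_table(data, label_column)
  counts <- table(parts$y)
  if (any(counts < k)) {
    abort(sprintf(
      "Every class needs at least k = %d members for stratified folds; smallest class has %d. Reduce k or add data.",
      k, min(counts)), class = "seizecca_error_stratification")
  }
  folds <- stratified_folds(parts$y, k, seed)
  classes <- sort(unique(parts$y))
  fold_reports <- vector("list", k)
  fold_confusions <- vector("list", k)
  predictions <- vector("list", k)
  for (f in seq_len(k)) {
    test <- folds == f
    model <- fit(data[!test, , drop = FALSE])
    pred <- predict_fn(model, data[test, , drop = FALSE])
    cm <- confusion(parts$y[test], pred$.pred_class, classes)
    fold_confusions[[f]] <- cm
    fold_reports[[f]] <- multiclass_metrics(cm)
    predictions[[f]] <- dplyr::bind_cols(
      tibble::tibble(row = which(test), fold = f, actual = parts$y[test]),
      pred
    )
  }
  pooled_cm <- Reduce(`+`, lapply(fold_confusions, unclass))
  pooled_cm <- confusion_as_matrix(pooled_cm)
  pooled <- multiclass_metrics(pooled_cm)
  predictions <- dplyr::bind_rows(predictions)
  score_cols <- grep("^\\.score_", names(predictions), value = TRUE)
  roc <- NULL
  macro_auc <- NA_real_
  if (length(score_cols) > 0) {
    roc <- roc_curve(predictions[score_cols], predictions$actual)
    macro_auc <- attr(roc, "macro_auc")
  }
  structure(
    list(fold_reports = fold_reports, pooled = pooled,
         pooled_confusion = pooled_cm, fold_assignments = folds,
         predictions = predictions, macro_auc = macro_auc, roc = roc,
         k = k, seed = seed),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold stratified cross-validation\n", x$k))
  cat(sprintf("Pooled accuracy: %.4f", x$pooled$accuracy))
  if (!is.na(x$macro_auc)) cat(sprintf("  macro AUC: %.4f", x$macro_auc))
  cat("\nPooled macro metrics:\n")
  print(x$pooled$averaged)
  invisible(x)
}
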