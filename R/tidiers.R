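#' Tidy the per-epoch training log of a DCSAE model
#'
#' @param x A fitted `dcsae` model.
#' @param ... Unused.
#' @return A tibble with one row per epoch and loss component columns.
#' @export
tidy.dcsae <- function(x, ...) {
  x$training_log
}

#' One-row summary of a fitted DCSAE model
#'
#' @param x A fitted `dcsae` model.
#' @param ... Unused.
#' @return A one-row tibble: canonical dimensions, achieved correlation,
#'   final total loss, epochs, classes, features.
#' @export
glance.dcsae <- function(x, ...) {
  last <- x$training_log[nrow(x$training_log), ]
  tibble::tibble(
    canonical_dims = x$dims,
    correlation = last$correlation,
    total_loss = last$total,
    epochs = x$config$epochs,
    n_classes = length(x$classes),
    n_features = length(x$features),
    n_train = x$n_train
  )
}

#' Tidy an optimizer convergence trace
#'
#' @param x A `coa_result`, `coa_selection`, `kha_result` or `kha_tuning`.
#' @param ... Unused.
#' @return The trace tibble (iteration, incumbent best cost, and decoded
#'   parameters for tuning objects).
#' @export
tidy.coa_result <- function(x, ...) x$trace

#' @rdname tidy.coa_result
#' @export
tidy.coa_selection <- function(x, ...) x$trace

#' @rdname tidy.coa_result
#' @export
tidy.kha_result <- function(x, ...) x$trace

#' @rdname tidy.coa_result
#' @export
tidy.kha_tuning <- function(x, ...) x$trace

#' One-row summary of a feature-selection run
#'
#' @param x A `coa_selection` from [select_features()].
#' @param ... Unused.
#' @return A one-row tibble: selected count, total features, best cost,
#'   error weight.
#' @export
glance.coa_selection <- function(x, ...) {
  tibble::tibble(
    n_selected = x$n_selected,
    n_total = length(x$mask),
    best_cost = x$best_cost,
    alpha_weight = x$alpha_weight,
    iterations = x$config$max_iterations
  )
}

#' Tidy a confusion matrix into long counts
#'
#' @param x A [confusion()] matrix.
#' @param ... Unused.
#' @return A tibble with `actual`, `predicted`, `count`.
#' @export
tidy.confusion_matrix <- function(x, ...) {
  df <- as.data.frame(as.table(unclass(x)), responseName = "count")
  names(df)[1:2] <- c("actual", "predicted")
  tibble::as_tibble(df)
}

#' Tidy a metrics report into per-class rows
#'
#' @param x A [multiclass_metrics()] report.
#' @param ... Unused.
#' @return The per-class tibble.
#' @export
tidy.metrics_report <- function(x, ...) x$per_class

#' One-row macro summary of a metrics report
#'
#' @param x A [multiclass_metrics()] report.
#' @param ... Unused.
#' @return A one-row tibble: accuracy plus macro-averaged metrics.
#' @export
glance.metrics_report <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(accuracy = x$accuracy), x$averaged)
}

#' Tidy cross-validation results into per-fold rows
#'
#' @param x A [kfold_evaluate()] result.
#' @param ... Unused.
#' @return A tibble with one row per fold: accuracy and macro metrics.
#' @export
tidy.cv_result <- function(x, ...) {
  rows <- purrr::imap(x$fold_reports, function(rep, f) {
    dplyr::bind_cols(tibble::tibble(fold = f, accuracy = rep$accuracy),
                     rep$averaged)
  })
  dplyr::bind_rows(rows)
}

#' One-row pooled summary of cross-validation results
#'
#' @param x A [kfold_evaluate()] result.
#' @param ... Unused.
#' @return A one-row tibble: pooled accuracy, macro metrics, macro AUC, k.
#' @export
glance.cv_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(accuracy = x$pooled$accuracy),
    x$pooled$averaged,
    tibble::tibble(macro_auc = x$macro_auc, k = x$k)
  )
}
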