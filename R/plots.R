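#' Plot an optimizer convergence trace
#'
#' Best-cost-so-far per iteration for a [coa_optimize()] or [kha_optimize()]
#' result (or a selection/tuning object carrying a `trace`).
#'
#' @param object A `coa_result`, `coa_selection`, `kha_result` or
#'   `kha_tuning` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coa_result <- function(object, ...) {
  plot_trace(object$trace, names(object$trace)[2], "Coyote optimization convergence")
}

#' @rdname autoplot.coa_result
#' @export
autoplot.coa_selection <- function(object, ...) {
  plot_trace(object$trace, "best_cost", "Feature-selection convergence")
}

#' @rdname autoplot.coa_result
#' @export
autoplot.kha_result <- function(object, ...) {
  plot_trace(object$trace, "best_fitness", "Krill herd convergence")
}

#' @rdname autoplot.coa_result
#' @export
autoplot.kha_tuning <- function(object, ...) {
  plot_trace(object$trace[, 1:2], "best_fitness",
             "Hyperparameter tuning convergence")
}

plot_trace <- function(trace, value_col, title) {
  ggplot2::ggplot(trace, ggplot2::aes(x = .data$iteration, y = .data[[value_col]])) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Iteration", y = "Best cost", title = title) +
    ggplot2::theme_minimal()
}

#' Plot DCSAE training loss components
#'
#' Per-epoch curves of the total loss, the canonical correlation and the
#' reconstruction and sparsity components.
#'
#' @param object A fitted `dcsae` model.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dcsae <- function(object, ...) {
  long <- tidyr::pivot_longer(object$training_log, -"epoch",
                              names_to = "component", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = "Epoch", y = NULL, title = "DCSAE training components") +
    ggplot2::theme_minimal()
}

#' Plot one-vs-rest ROC curves
#'
#' @param object A [roc_curve()] result.
#' @param ... Unused.
#' @return A ggplot object with one curve per class and the chance diagonal.
#' @export
autoplot.roc_curve <- function(object, ...) {
  aucs <- attr(object, "auc")
  labels <- setNames(sprintf("%s (AUC %.3f)", aucs$class, aucs$auc), aucs$class)
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$fpr, y = .data$tpr,
                               colour = .data$class)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::scale_colour_discrete(labels = labels) +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  colour = "Class", title = "One-vs-rest ROC") +
    ggplot2::theme_minimal()
}

#' Heatmap of a confusion matrix
#'
#' @param cm A [confusion()] matrix or a `cv_result`.
#' @return A ggplot tile plot with counts.
#' @export
plot_confusion <- function(cm) {
  if (inherits(cm, "cv_result")) cm <- cm$pooled_confusion
  df <- as.data.frame(as.table(unclass(cm)), responseName = "count")
  names(df)[1:2] <- c("actual", "predicted")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$actual,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(title = "Confusion matrix") +
    ggplot2::theme_minimal()
}
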