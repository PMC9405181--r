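#' Read a UCI-layout EEG feature table
#'
#' Reads a comma-delimited table with one row per one-second EEG segment:
#' numeric feature columns (`X1`..`X178` in the reference layout) plus one
#' integer label column. Raw labels follow the UCI convention `1..5` with
#' `1` = seizure activity; they can be remapped on read to the binary or
#' multiclass scheme used throughout the package (`0` = seizure).
#'
#' @param path Path to a CSV file with a header row.
#' @param label_column Name of the label column. Default `"y"`.
#' @param label_scheme One of `"raw"` (keep labels as stored), `"binary"`
#'   (raw 1 -> 0 seizure, raw 2..5 -> 1 non-seizure) or `"multiclass"`
#'   (raw k -> k - 1).
#' @return A tibble with the feature columns and the integer label column,
#'   with attribute `label_scheme` recording the applied scheme.
#' @seealso [remap_labels()], [write_uci_csv()]
#' @export
#' @examples
#' path <- tempfile(fileext = ".csv")
#' tbl <- simulate_eeg_segments(n_per_class = 5, n_classes = 2, n_features = 6)
#' write_uci_csv(tbl, path)
#' read_feature_table(path)
read_feature_table <- function(path, label_column = "y",
                               label_scheme = c("raw", "binary", "multiclass")) {
  label_scheme <- rlang::arg_match(label_scheme)
  if (!file.exists(path)) stop_parse(sprintf("File not found: %s", path))
  data <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) stop_parse(sprintf("Could not parse '%s': %s", path, conditionMessage(e)))
  )
  if (nrow(data) == 0L || ncol(data) == 0L) {
    stop_parse(sprintf("File '%s' contains no data rows.", path))
  }
  if (!label_column %in% names(data)) {
    stop_label(sprintf("Label column '%s' not found in '%s'.", label_column, path))
  }
  feat_cols <- setdiff(names(data), label_column)
  if (length(feat_cols) == 0L) stop_parse("No feature columns found.")
  for (col in feat_cols) {
    v <- data[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1] %||% 1L
      stop_parse(sprintf("Non-numeric value in column '%s', row %d.", col, bad))
    }
    if (anyNA(v) || any(!is.finite(v))) {
      bad <- which(!is.finite(v))[1]
      stop_parse(sprintf("Missing or non-finite value in column '%s', row %d.", col, bad))
    }
  }
  labels <- data[[label_column]]
  if (anyNA(labels)) stop_label("Missing values in the label column.")
  data[[label_column]] <- remap_labels(labels, label_scheme)
  out <- tibble::as_tibble(data)
  attr(out, "label_scheme") <- label_scheme
  out
}

#' Remap raw UCI labels to the binary or multiclass scheme
#'
#' The UCI epileptic-seizure table codes segments `1..5` with `1` = ictal
#' (seizure) activity. The package's schemes put the seizure class at `0`:
#' binary maps raw `1 -> 0` and raw `2..5 -> 1`; multiclass maps raw
#' `k -> k - 1`.
#'
#' @param labels Integer vector of raw labels.
#' @param scheme `"raw"`, `"binary"` or `"multiclass"`.
#' @return Integer vector of remapped labels.
#' @export
remap_labels <- function(labels, scheme = c("raw", "binary", "multiclass")) {
  scheme <- rlang::arg_match(scheme)
  labels <- as.integer(labels)
  if (scheme == "raw") return(labels)
  bad <- setdiff(unique(labels), 1:5)
  if (length(bad) > 0) {
    stop_label(sprintf(
      "Label value(s) %s invalid under scheme '%s' (raw labels must be 1..5).",
      paste(bad, collapse = ", "), scheme
    ))
  }
  if (scheme == "binary") ifelse(labels == 1L, 0L, 1L) else labels - 1L
}

#' Fit per-feature min-max normalization parameters
#'
#' Records the column-wise minima and maxima of the feature columns. Fit on
#' training rows only and apply to held-out rows with [apply_minmax()] so no
#' information leaks across folds.
#'
#' @param data Feature table (tibble) including the label column.
#' @param label_column Name of the label column to leave untouched.
#' @return A tibble of class `minmax_params` with columns `feature`,
#'   `x_min`, `x_max`.
#' @export
fit_minmax <- function(data, label_column = "y") {
  parts <- split_table(data, label_column)
  if (nrow(parts$x) < 1L) stop_shape("Need at least one row to fit normalization.")
  out <- tibble::tibble(
    feature = parts$features,
    x_min = unname(apply(parts$x, 2, min)),
    x_max = unname(apply(parts$x, 2, max))
  )
  class(out) <- c("minmax_params", class(out))
  out
}

#' Apply min-max normalization
#'
#' Maps each feature cell to `(x - x_min) / (x_max - x_min)` using fitted
#' extremes, so values inside the fitted range land in `[0, 1]`. Constant
#' columns (`x_max == x_min`) map to 0. Held-out values outside the fitted
#' range are not clipped, preserving linearity of the transform.
#'
#' @param data Feature table including the label column.
#' @param params A `minmax_params` object from [fit_minmax()].
#' @param label_column Name of the label column.
#' @return The normalized feature table (tibble).
#' @export
apply_minmax <- function(data, params, label_column = "y") {
  parts <- split_table(data, label_column)
  if (!identical(parts$features, params$feature)) {
    stop_shape("Feature columns do not match the fitted normalization parameters.")
  }
  range <- params$x_max - params$x_min
  scale <- ifelse(range > 0, 1 / pmax(range, .Machine$double.xmin), 0)
  z <- sweep(parts$x, 2, params$x_min, "-")
  z <- sweep(z, 2, scale, "*")
  out <- tibble::as_tibble(as.data.frame(z))
  out[[label_column]] <- data[[label_column]]
  out[c(params$feature, label_column)]
}

#' Invert min-max normalization
#'
#' Recovers original-scale values via `x_min + z * (x_max - x_min)`.
#' Constant columns are restored to their constant `x_min`.
#'
#' @inheritParams apply_minmax
#' @return Feature table on the original scale.
#' @export
invert_minmax <- function(data, params, label_column = "y") {
  parts <- split_table(data, label_column)
  if (!identical(parts$features, params$feature)) {
    stop_shape("Feature columns do not match the fitted normalization parameters.")
  }
  range <- params$x_max - params$x_min
  x <- sweep(parts$x, 2, range, "*")
  x <- sweep(x, 2, params$x_min, "+")
  out <- tibble::as_tibble(as.data.frame(x))
  out[[label_column]] <- data[[label_column]]
  out[c(params$feature, label_column)]
}
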