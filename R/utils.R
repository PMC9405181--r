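# Shared internal helpers: typed conditions, seed derivation, matrix views.

stop_parse <- function(msg, ...) abort(msg, class = "seizecca_error_parse", ...)
stop_label <- function(msg, ...) abort(msg, class = "seizecca_error_label", ...)
stop_shape <- function(msg, ...) abort(msg, class = "seizecca_error_shape", ...)
stop_config <- function(msg, ...) abort(msg, class = "seizecca_error_config", ...)
stop_numeric <- function(msg, ...) abort(msg, class = "seizecca_error_numeric", ...)

# Deterministic sub-seed from a master seed; kept inside 32-bit range.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 2011L + as.integer(offset) %% 2011L
}

# Split a feature table into the numeric matrix and the label vector.
split_table <- function(data, label_column = "y") {
  if (!is.data.frame(data)) stop_shape("`data` must be a data frame.")
  if (!label_column %in% names(data)) {
    stop_label(sprintf("Label column '%s' not found.", label_column))
  }
  x <- as.matrix(data[, setdiff(names(data), label_column), drop = FALSE])
  if (!is.numeric(x)) stop_parse("All feature columns must be numeric.")
  list(
    x = x,
    y = as.integer(data[[label_column]]),
    features = setdiff(names(data), label_column)
  )
}

# Stratified fold assignment: within each class, cycle fold ids over a
# seeded permutation so fold sizes differ by at most one per class.
stratified_folds <- function(labels, k, seed) {
  n <- length(labels)
  folds <- integer(n)
  set.seed(derive_seed(seed, 77L))
  for (cls in sort(unique(labels))) {
    idx <- which(labels == cls)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
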