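#' Simulate UCI-layout EEG segment tables with planted class structure
#'
#' Generates a deterministic synthetic feature table in the layout of the
#' UCI epileptic-seizure recognition dataset: one row per one-second EEG
#' segment, `n_features` numeric columns (`X1`..`Xd`, default 178, mimicking
#' a 178 Hz segment), and an integer class column `y` in `0..n_classes - 1`.
#'
#' Two waveform modes are available:
#' \describe{
#'   \item{`iid-gaussian`}{Every cell is `N(0, noise_sd^2)` noise; rows of
#'     class `c` additionally receive a mean shift of
#'     `c * class_separation * noise_sd` on the planted informative columns,
#'     so the separation is expressed in units of the noise SD and class 0
#'     is the unshifted reference.}
#'   \item{`sinusoid-segment`}{Each row is one second of a sinusoid at a
#'     class-specific frequency (`3 + 4c` Hz) with a random phase, sampled at
#'     `n_features` points, plus Gaussian noise. All columns carry class
#'     information; `informative` is ignored.}
#' }
#'
#' Classes are balanced (`n_per_class` rows each) unless `class_sizes`
#' overrides them, e.g. `c(2300, 9200)` reproduces the 1:4 binary imbalance
#' of the reference dataset. Output is fully determined by `seed`.
#'
#' @param n_per_class Rows per class (ignored when `class_sizes` is given).
#' @param n_classes Number of classes, 2 to 5.
#' @param n_features Number of feature columns (default 178).
#' @param informative Integer positions (1-based) of the class-informative
#'   columns. Default: 8 evenly spaced columns (or all columns if fewer).
#' @param class_separation Mean shift per class step, in units of `noise_sd`.
#' @param noise_sd Noise standard deviation.
#' @param waveform `"iid-gaussian"` or `"sinusoid-segment"`.
#' @param class_sizes Optional explicit per-class row counts (length
#'   `n_classes`), overriding `n_per_class`.
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A tibble with columns `X1..Xd` and integer `y`, carrying
#'   attributes `informative_indices` (ground-truth planted columns) and
#'   `synth_config`.
#' @export
#' @examples
#' tbl <- simulate_eeg_segments(n_per_class = 50, n_classes = 2,
#'                              n_features = 30, informative = c(3, 7, 12),
#'                              class_separation = 2, seed = 1)
#' table(tbl$y)
simulate_eeg_segments <- function(n_per_class = 100,
                                  n_classes = 2,
                                  n_features = 178,
                                  informative = NULL,
                                  class_separation = 1,
                                  noise_sd = 1,
                                  waveform = c("iid-gaussian", "sinusoid-segment"),
                                  class_sizes = NULL,
                                  seed = 1) {
  waveform <- rlang::arg_match(waveform)
  if (!is_scalar_number(n_classes) || n_classes < 2 || n_classes > 5) {
    stop_config("`n_classes` must be between 2 and 5.")
  }
  if (!is_scalar_number(n_features) || n_features < 1) {
    stop_config("`n_features` must be a positive integer.")
  }
  if (!is_scalar_number(class_separation) || class_separation < 0) {
    stop_config("`class_separation` must be a non-negative number.")
  }
  if (!is_scalar_number(noise_sd) || noise_sd <= 0) {
    stop_config("`noise_sd` must be positive.")
  }
  if (is.null(class_sizes)) {
    if (!is_scalar_number(n_per_class) || n_per_class < 1) {
      stop_config("`n_per_class` must be a positive integer.")
    }
    class_sizes <- rep(as.integer(n_per_class), n_classes)
  }
  if (length(class_sizes) != n_classes || any(class_sizes < 1)) {
    stop_config("`class_sizes` must give a positive count for every class.")
  }
  if (is.null(informative)) {
    informative <- unique(round(seq(1, n_features, length.out = min(8, n_features))))
  }
  informative <- as.integer(informative)
  if (any(informative < 1L | informative > n_features)) {
    stop_config("`informative` indices must lie in 1..n_features.")
  }

  n <- sum(class_sizes)
  labels <- rep(seq_len(n_classes) - 1L, times = class_sizes)
  set.seed(derive_seed(seed, 11L))
  if (waveform == "iid-gaussian") {
    x <- matrix(rnorm(n * n_features, sd = noise_sd), nrow = n)
    shift <- labels * class_separation * noise_sd
    x[, informative] <- x[, informative] + shift
  } else {
    t_grid <- (seq_len(n_features) - 1L) / n_features
    freq <- 3 + 4 * labels
    phase <- runif(n, 0, 2 * pi)
    x <- sin(outer(2 * pi * freq, t_grid) + phase) +
      matrix(rnorm(n * n_features, sd = noise_sd), nrow = n)
    informative <- seq_len(n_features)
  }
  colnames(x) <- paste0("X", seq_len(n_features))
  out <- tibble::as_tibble(as.data.frame(x))
  out$y <- labels
  attr(out, "informative_indices") <- informative
  attr(out, "synth_config") <- list(
    n_per_class = n_per_class, n_classes = n_classes, n_features = n_features,
    informative = informative, class_separation = class_separation,
    noise_sd = noise_sd, waveform = waveform, class_sizes = class_sizes,
    seed = seed
  )
  out
}

#' Write a feature table as a UCI-layout CSV
#'
#' Writes the table comma-delimited with a header (`X1..Xd, y`), labels as
#' integers and features at full double precision so that
#' [read_feature_table()] round-trips the matrix losslessly.
#'
#' @param data Feature table (tibble) with a label column.
#' @param path Output file path.
#' @param label_column Name of the label column.
#' @return `path`, invisibly.
#' @export
write_uci_csv <- function(data, path, label_column = "y") {
  parts <- split_table(data, label_column)
  out <- data
  out[[label_column]] <- as.integer(data[[label_column]])
  out <- out[c(parts$features, label_column)]
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
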