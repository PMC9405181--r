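#' Pipeline configuration
#'
#' Assembles the nested configuration for [run_pipeline()]: data source,
#' min-max normalization, coyote feature selection, optional krill-herd
#' tuning, DCSAE training and stratified k-fold evaluation. Training
#' defaults follow the reference settings (learning rate 0.01, dropout 0.5,
#' 50 epochs) and evaluation defaults to 10-fold cross-validation. Krill
#' tuning is off by default because it multiplies the training cost.
#'
#' @param path CSV input path (UCI layout); `NULL` when `synth` is given.
#' @param synth Named list of [simulate_eeg_segments()] arguments used to
#'   generate the input table instead of reading a file.
#' @param label_column,label_scheme Passed to [read_feature_table()].
#' @param select Named list overriding the selection stage: `enabled`,
#'   `alpha_weight`, `threshold`, `n_packs`, `coyotes_per_pack`,
#'   `max_iterations`.
#' @param tune Named list overriding the tuning stage: `enabled`, `n_krill`,
#'   `max_iterations`, `inner_epochs`, `valid_fraction`.
#' @param train Named list of [dcsae_config()] overrides.
#' @param evaluate Named list: `k` (folds).
#' @param seed Master seed; every stage seed is derived from it.
#' @return A nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, synth = NULL,
                            label_column = "y", label_scheme = "raw",
                            select = list(), tune = list(), train = list(),
                            evaluate = list(), seed = 1) {
  config <- list(
    data = list(path = path, synth = synth,
                label_column = label_column, label_scheme = label_scheme),
    select = utils::modifyList(
      list(enabled = TRUE, alpha_weight = 0.99, threshold = 0.5,
           n_packs = 3, coyotes_per_pack = 6, max_iterations = 30),
      select
    ),
    tune = utils::modifyList(
      list(enabled = FALSE, n_krill = 8, max_iterations = 10,
           inner_epochs = 10, valid_fraction = 0.25),
      tune
    ),
    train = train,
    evaluate = utils::modifyList(list(k = 10), evaluate),
    seed = as.integer(seed)
  )
  class(config) <- "pipeline_config"
  validate_pipeline_config(config)
  config
}

validate_pipeline_config <- function(config) {
  data <- config$data
  if (is.null(data) || (is.null(data$path) && is.null(data$synth))) {
    stop_config("The data section must provide either `path` or `synth`.")
  }
  if (!is.null(data$path) && !is.null(data$synth)) {
    stop_config("Provide `path` or `synth`, not both.")
  }
  if (config$evaluate$k < 2) stop_config("`evaluate$k` must be at least 2.")
  # constructing the training config validates every train override
  do.call(dcsae_config, config$train)
  invisible(config)
}

#' Read a pipeline configuration from a YAML file
#'
#' The file mirrors the sections of [pipeline_config()] (`data`, `select`,
#' `tune`, `train`, `evaluate`, `seed`).
#'
#' @param path YAML file path.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("Config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  pipeline_config(
    path = raw$data$path,
    synth = raw$data$synth,
    label_column = raw$data$label_column %||% "y",
    label_scheme = raw$data$label_scheme %||% "raw",
    select = raw$select %||% list(),
    tune = raw$tune %||% list(),
    train = raw$train %||% list(),
    evaluate = raw$evaluate %||% list(),
    seed = raw$seed %||% 1
  )
}

#' Serialize / restore a fitted DCSAE model as JSON
#'
#' Writes every parameter array, the canonical directions `U` and `V`, the
#' projection means, the class centroids and the full configuration to a
#' single JSON file at full double precision.
#'
#' @param model A fitted `dcsae` object.
#' @param path Output (input) JSON path.
#' @return `path` invisibly; `load_dcsae()` returns the restored model.
#' @export
save_dcsae <- function(model, path) {
  nets <- purrr::map(model$nets, function(net) {
    net$vel <- NULL  # optimizer state is not part of the fitted model
    net
  })
  payload <- list(
    nets = nets, u = model$u, v = model$v,
    singular_values = model$singular_values,
    h1_mean = model$h1_mean, h2_mean = model$h2_mean,
    centroids = unclass(model$centroids), classes = model$classes,
    features = model$features, dims = model$dims,
    view = model$view, label_column = model$label_column,
    n_train = model$n_train,
    config = unclass(model$config),
    training_log = model$training_log
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_dcsae
#' @export
load_dcsae <- function(path) {
  if (!file.exists(path)) stop_parse(sprintf("Model file not found: %s", path))
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyMatrix = TRUE,
                            simplifyDataFrame = FALSE)
  as_mat <- function(m) if (is.matrix(m)) m else matrix(m, nrow = 1)
  fix_net <- function(net) {
    net$layers <- purrr::map(net$layers, function(l) {
      list(w = as_mat(l$w), b = as.numeric(l$b))
    })
    net$linear_out <- isTRUE(net$linear_out)
    net
  }
  model <- list(
    nets = purrr::map(raw$nets, fix_net),
    u = as_mat(raw$u), v = as_mat(raw$v),
    singular_values = as.numeric(raw$singular_values),
    h1_mean = as.numeric(raw$h1_mean), h2_mean = as.numeric(raw$h2_mean),
    centroids = as_mat(raw$centroids), classes = as.integer(raw$classes),
    features = as.character(raw$features), dims = as.integer(raw$dims),
    view = raw$view, label_column = raw$label_column,
    n_train = raw$n_train,
    config = structure(raw$config, class = "dcsae_config"),
    training_log = dplyr::bind_rows(purrr::map(raw$training_log, tibble::as_tibble))
  )
  rownames(model$centroids) <- model$classes
  class(model) <- "dcsae"
  model
}

stage_wrap <- function(stage, manifest, out_dir, expr) {
  t0 <- Sys.time()
  result <- tryCatch(expr, error = function(e) {
    manifest$failed_stage <- stage
    manifest$error <- conditionMessage(e)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    abort(sprintf("Stage '%s' failed: %s", stage, conditionMessage(e)),
          class = "seizecca_error_stage", parent = e)
  })
  list(result = result,
       seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
}

#' Run the full seizure-classification pipeline
#'
#' Executes, in order: data loading (file or synthetic generation), min-max
#' normalization, coyote feature selection, optional krill-herd
#' hyperparameter tuning, DCSAE training and stratified k-fold evaluation.
#' Normalization and feature selection are re-fitted inside every training
#' fold so no information leaks into the held-out folds; hyperparameter
#' tuning (when enabled) runs once on the full table with its own internal
#' validation split, and the winning configuration is reused across folds.
#' A final model is fitted on all rows for the persisted artifacts.
#'
#' Artifacts written to `out_dir`: the input table (`data.csv`, when
#' generated), `normalization.csv`, `selected_features.txt` (+ JSON
#' sidecar), `tuning_trace.csv` and `tuned_config.json` (when tuning),
#' `model.json`, `metrics_folds.csv` (per-fold rows plus an average row),
#' `metrics_pooled.json`, `roc_points.csv` and `manifest.json` (seeds,
#' versions, stage timings). Rerunning with the same configuration
#' reproduces every numeric output.
#'
#' @param config A [pipeline_config()] or the path to a YAML config file.
#' @param out_dir Output directory (created if missing).
#' @return A list of class `pipeline_result`: `cv` ([kfold_evaluate()]
#'   result), `selection`, `tuning` (or `NULL`), `model`, `config`,
#'   `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("seizecca_run_")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("seizecca")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    timings = list()
  )

  # --- load ---------------------------------------------------------------
  st <- stage_wrap("load", manifest, out_dir, {
    if (!is.null(config$data$synth)) {
      args <- config$data$synth
      args$seed <- args$seed %||% config$seed
      tbl <- do.call(simulate_eeg_segments, args)
      write_uci_csv(tbl, file.path(out_dir, "data.csv"),
                    config$data$label_column %||% "y")
      tbl
    } else {
      read_feature_table(config$data$path, config$data$label_column,
                         config$data$label_scheme)
    }
  })
  data <- st$result
  manifest$timings$load <- st$seconds
  label_column <- config$data$label_column %||% "y"

  # --- tune (optional, once, internal validation split) -------------------
  tuning <- NULL
  train_overrides <- config$train
  train_overrides$seed <- train_overrides$seed %||% derive_seed(config$seed, 31L)
  base_config <- do.call(dcsae_config, train_overrides)
  if (isTRUE(config$tune$enabled)) {
    st <- stage_wrap("tune", manifest, out_dir, {
      params <- fit_minmax(data, label_column)
      normalized <- apply_minmax(data, params, label_column)
      tune_dcsae(
        normalized, label_column,
        kha = kha_config(dim = nrow(default_tuning_space()),
                         n_krill = config$tune$n_krill,
                         max_iterations = config$tune$max_iterations,
                         seed = derive_seed(config$seed, 41L)),
        base = base_config,
        valid_fraction = config$tune$valid_fraction,
        inner_epochs = config$tune$inner_epochs,
        seed = derive_seed(config$seed, 43L)
      )
    })
    tuning <- st$result
    manifest$timings$tune <- st$seconds
    base_config <- tuning$best_config
    readr::write_csv(tuning$trace, file.path(out_dir, "tuning_trace.csv"),
                     progress = FALSE)
    jsonlite::write_json(unclass(tuning$best_config),
                         file.path(out_dir, "tuned_config.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  # --- fold pipeline: normalize -> select -> train ------------------------
  select_cfg <- config$select
  fit_fold <- function(train_data) {
    params <- fit_minmax(train_data, label_column)
    normalized <- apply_minmax(train_data, params, label_column)
    selection <- NULL
    if (isTRUE(select_cfg$enabled)) {
      d <- ncol(normalized) - 1L
      selection <- select_features(
        normalized, label_column,
        coa = coa_config(dim = d, n_packs = select_cfg$n_packs,
                         coyotes_per_pack = select_cfg$coyotes_per_pack,
                         max_iterations = select_cfg$max_iterations,
                         lower = 0, upper = 1,
                         seed = derive_seed(config$seed, 51L)),
        alpha_weight = select_cfg$alpha_weight,
        threshold = select_cfg$threshold,
        seed = derive_seed(config$seed, 53L)
      )
      normalized <- normalized[c(selection$features, label_column)]
    }
    model <- train_dcsae(normalized, label_column, config = base_config)
    list(params = params, selection = selection, model = model)
  }
  predict_fold <- function(fitted, test_data) {
    normalized <- apply_minmax(test_data, fitted$params, label_column)
    predict(fitted$model, normalized)
  }

  # --- evaluate ------------------------------------------------------------
  st <- stage_wrap("evaluate", manifest, out_dir, {
    kfold_evaluate(data, fit_fold, predict_fold, k = config$evaluate$k,
                   seed = derive_seed(config$seed, 61L),
                   label_column = label_column)
  })
  cv <- st$result
  manifest$timings$evaluate <- st$seconds

  # --- final fit on all rows ----------------------------------------------
  st <- stage_wrap("train", manifest, out_dir, fit_fold(data))
  final <- st$result
  manifest$timings$train <- st$seconds

  readr::write_csv(fit_minmax(data, label_column),
                   file.path(out_dir, "normalization.csv"), progress = FALSE)
  if (!is.null(final$selection)) {
    write_feature_mask(final$selection, file.path(out_dir, "selected_features.txt"))
  }
  save_dcsae(final$model, file.path(out_dir, "model.json"))
  write_metrics_report(cv, out_dir)

  manifest$n_rows <- nrow(data)
  manifest$n_features <- ncol(data) - 1L
  manifest$n_selected <- final$selection$n_selected %||% (ncol(data) - 1L)
  manifest$stage_seeds <- list(
    train = base_config$seed, select = derive_seed(config$seed, 51L),
    folds = derive_seed(config$seed, 61L)
  )
  if (!is.null(base_config)) manifest$train_config <- unclass(base_config)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  structure(
    list(cv = cv, selection = final$selection, tuning = tuning,
         model = final$model, config = config, out_dir = out_dir),
    class = "pipeline_result"
  )
}

# Per-fold metric rows (plus the average row), pooled JSON and ROC points.
write_metrics_report <- function(cv, out_dir) {
  rows <- purrr::imap(cv$fold_reports, function(rep, f) {
    dplyr::bind_cols(tibble::tibble(fold = as.character(f),
                                    accuracy = rep$accuracy),
                     rep$averaged)
  })
  folds_tbl <- dplyr::bind_rows(rows)
  avg <- dplyr::summarise(folds_tbl, dplyr::across(dplyr::where(is.numeric), mean))
  folds_tbl <- dplyr::bind_rows(folds_tbl,
                                dplyr::bind_cols(tibble::tibble(fold = "average"), avg))
  readr::write_csv(folds_tbl, file.path(out_dir, "metrics_folds.csv"),
                   progress = FALSE)
  pooled <- list(
    accuracy = cv$pooled$accuracy,
    averaged = as.list(cv$pooled$averaged),
    per_class = cv$pooled$per_class,
    macro_auc = if (is.na(cv$macro_auc)) NULL else cv$macro_auc,
    confusion = unclass(cv$pooled_confusion)
  )
  jsonlite::write_json(pooled, file.path(out_dir, "metrics_pooled.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  if (!is.null(cv$roc)) {
    readr::write_csv(tibble::as_tibble(cv$roc), file.path(out_dir, "roc_points.csv"),
                     progress = FALSE)
  }
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("seizecca pipeline run:", x$out_dir, "\n")
  if (!is.null(x$selection)) {
    cat(sprintf("Selected %d features (best cost %.4f)\n",
                x$selection$n_selected, x$selection$best_cost))
  }
  print(x$cv)
  invisible(x)
}
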