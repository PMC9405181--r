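#' Krill herd optimizer configuration
#'
#' Settings for the krill herd algorithm (KHA), a swarm optimizer whose
#' position update integrates three motions: neighbour-induced movement
#' toward/away from other krill, foraging toward a fitness-weighted food
#' centroid, and random physical diffusion that decays linearly to zero.
#'
#' Defaults follow the standard krill-herd constants: maximal induced speed
#' `n_max = 0.01`, inertia weights decaying linearly from 0.9 to 0.1 over
#' the iterations, foraging speed 0.02, maximal diffusion 0.005, and a step
#' scale `dt = ct * 0.5 * sum(upper - lower)` with `ct = 0.5`.
#'
#' @param dim Problem dimension.
#' @param n_krill Swarm size.
#' @param max_iterations Iteration budget `I_max`.
#' @param n_max Maximal induced speed.
#' @param inertia_start,inertia_end Linear inertia schedule endpoints for
#'   both the induced-motion and foraging inertia.
#' @param foraging_speed Foraging speed `V_f`.
#' @param diffusion_max Maximal diffusion speed `D_max`.
#' @param ct Step-scale factor in `(0, 2]`.
#' @param lower,upper Bounds; scalars are recycled.
#' @param seed Integer seed.
#' @return A list of class `kha_config`.
#' @export
kha_config <- function(dim,
                       n_krill = 20,
                       max_iterations = 100,
                       n_max = 0.01,
                       inertia_start = 0.9,
                       inertia_end = 0.1,
                       foraging_speed = 0.02,
                       diffusion_max = 0.005,
                       ct = 0.5,
                       lower = 0,
                       upper = 1,
                       seed = 1) {
  if (!is_scalar_number(dim) || dim < 1) stop_config("`dim` must be a positive integer.")
  if (n_krill < 2 || max_iterations < 1) {
    stop_config("`n_krill` must be >= 2 and `max_iterations` positive.")
  }
  if (n_max <= 0 || foraging_speed <= 0 || diffusion_max <= 0 || ct <= 0) {
    stop_config("Speeds and `ct` must be positive.")
  }
  lower <- rep_len(lower, dim)
  upper <- rep_len(upper, dim)
  if (any(lower > upper)) stop_config("`lower` must not exceed `upper`.")
  structure(
    list(
      dim = as.integer(dim), n_krill = as.integer(n_krill),
      max_iterations = as.integer(max_iterations),
      n_max = n_max, inertia_start = inertia_start, inertia_end = inertia_end,
      foraging_speed = foraging_speed, diffusion_max = diffusion_max,
      ct = ct, lower = lower, upper = upper, seed = as.integer(seed)
    ),
    class = "kha_config"
  )
}

#' Linear inertia schedule
#'
#' Interpolates linearly from `inertia_start` at iteration 0 to
#' `inertia_end` at `max_iterations`; with the 0.9 -> 0.1 defaults the
#' midpoint iteration gives exactly 0.5.
#'
#' @param iteration Current iteration `I`.
#' @param config A [kha_config()].
#' @return Scalar inertia weight.
#' @export
kha_inertia <- function(iteration, config) {
  config$inertia_start +
    (config$inertia_end - config$inertia_start) * iteration / config$max_iterations
}

# Normalised fitness difference K_hat_ij and unit direction X_hat_ij used by
# the induced and foraging attraction terms. eps keeps denominators finite.
kha_eps <- 1e-10

khat <- function(k_i, k_j, k_best, k_worst) {
  (k_i - k_j) / (k_worst - k_best + kha_eps)
}

xhat <- function(x_from, x_to) {
  d <- x_to - x_from
  d / (sqrt(sum(d^2)) + kha_eps)
}

#' Neighbour-induced motion
#'
#' `N_new = n_max * (alpha_local + alpha_target) + omega_n * N_old`. The
#' local term sums `K_hat * X_hat` over neighbours within the sensing
#' distance (mean pairwise distance / 5); the target term attracts toward
#' the swarm's best krill with gain `C_best = 2 * (rand + I / I_max)`.
#'
#' @param positions `n x D` matrix of krill positions.
#' @param fitness Length-`n` fitness values (lower is better).
#' @param n_old `n x D` matrix of previous induced motions.
#' @param best_position,best_fitness Incumbent best.
#' @param iteration Current iteration.
#' @param config A [kha_config()].
#' @return `n x D` matrix of updated induced motions.
#' @export
induced_motion <- function(positions, fitness, n_old, best_position,
                           best_fitness, iteration, config) {
  n <- nrow(positions)
  omega <- kha_inertia(iteration, config)
  k_best <- min(fitness)
  k_worst <- max(fitness)
  pd <- as.matrix(stats::dist(positions))
  sensing <- rowSums(pd) / (5 * n)
  out <- matrix(0, n, ncol(positions))
  for (i in seq_len(n)) {
    alpha <- numeric(ncol(positions))
    nbr <- which(pd[i, ] < sensing[i] & seq_len(n) != i)
    for (j in nbr) {
      alpha <- alpha + khat(fitness[i], fitness[j], k_best, k_worst) *
        xhat(positions[i, ], positions[j, ])
    }
    c_best <- 2 * (runif(1) + iteration / config$max_iterations)
    alpha <- alpha + c_best *
      khat(fitness[i], best_fitness, k_best, k_worst) *
      xhat(positions[i, ], best_position)
    out[i, ] <- config$n_max * alpha + omega * n_old[i, ]
  }
  out
}

#' Fitness-weighted food position of the swarm
#'
#' The virtual food centroid `sum(X_i / K_i) / sum(1 / K_i)` (minimisation
#' weighting); a small epsilon keeps the weights finite at zero fitness.
#'
#' @inheritParams induced_motion
#' @return Length-`D` food position.
#' @export
food_position <- function(positions, fitness) {
  w <- 1 / (fitness + kha_eps)
  colSums(positions * w) / sum(w)
}

#' Foraging motion
#'
#' `F = V_f * (beta_food + beta_best) + omega_f * F_old`: attraction toward
#' the food centroid (gain `C_food = 2 * (1 - I / I_max)`) and toward the
#' incumbent best-so-far position, with linear foraging inertia.
#'
#' @inheritParams induced_motion
#' @param f_old `n x D` matrix of previous foraging motions.
#' @param food Length-`D` food position from [food_position()].
#' @param food_fitness Fitness evaluated at the food position.
#' @return `n x D` matrix of updated foraging motions.
#' @export
foraging_motion <- function(positions, fitness, f_old, food, food_fitness,
                            best_position, best_fitness, iteration, config) {
  n <- nrow(positions)
  omega <- kha_inertia(iteration, config)
  k_best <- min(fitness, best_fitness)
  k_worst <- max(fitness)
  c_food <- 2 * (1 - iteration / config$max_iterations)
  out <- matrix(0, n, ncol(positions))
  for (i in seq_len(n)) {
    beta <- c_food * khat(fitness[i], food_fitness, k_best, k_worst) *
      xhat(positions[i, ], food) +
      khat(fitness[i], best_fitness, k_best, k_worst) *
      xhat(positions[i, ], best_position)
    out[i, ] <- config$foraging_speed * beta + omega * f_old[i, ]
  }
  out
}

#' Physical (random) diffusion
#'
#' `D_i = D_max * (1 - I / I_max) * delta` with `delta` uniform in
#' `[-1, 1]^D`; the magnitude decays linearly and is exactly zero at the
#' final iteration.
#'
#' @param n Number of krill.
#' @param iteration Current iteration.
#' @param config A [kha_config()].
#' @return `n x D` matrix of diffusion speeds.
#' @export
physical_diffusion <- function(n, iteration, config) {
  decay <- config$diffusion_max * (1 - iteration / config$max_iterations)
  matrix(runif(n * config$dim, -1, 1), n, config$dim) * decay
}

#' One krill-herd step
#'
#' Updates all motions, moves every krill by `dt * (N + F + D)` with
#' `dt = ct * 0.5 * sum(upper - lower)`, clips to the bounds, re-evaluates
#' fitness and updates the incumbent (which therefore never worsens).
#'
#' @param state List with `positions`, `fitness`, `n_motion`, `f_motion`,
#'   `best_position`, `best_fitness` (as produced by [kha_optimize()]'s
#'   initialisation).
#' @param iteration Current iteration.
#' @param config A [kha_config()].
#' @param fitness_fn Function mapping a position to a finite fitness.
#' @return Updated state list.
#' @export
kha_step <- function(state, iteration, config, fitness_fn) {
  n_mot <- induced_motion(state$positions, state$fitness, state$n_motion,
                          state$best_position, state$best_fitness,
                          iteration, config)
  food <- food_position(state$positions, state$fitness)
  food_fit <- fitness_fn(food)
  f_mot <- foraging_motion(state$positions, state$fitness, state$f_motion,
                           food, food_fit, state$best_position,
                           state$best_fitness, iteration, config)
  d_mot <- physical_diffusion(config$n_krill, iteration, config)
  dt <- config$ct * 0.5 * sum(config$upper - config$lower)
  pos <- state$positions + dt * (n_mot + f_mot + d_mot)
  lo <- matrix(config$lower, nrow(pos), config$dim, byrow = TRUE)
  hi <- matrix(config$upper, nrow(pos), config$dim, byrow = TRUE)
  pos <- pmin(pmax(pos, lo), hi)
  fit <- apply(pos, 1, fitness_fn)
  if (any(!is.finite(fit))) stop_numeric("Fitness function returned a non-finite value.")
  best <- which.min(fit)
  if (fit[best] < state$best_fitness) {
    state$best_fitness <- fit[best]
    state$best_position <- pos[best, ]
  }
  state$positions <- pos
  state$fitness <- fit
  state$n_motion <- n_mot
  state$f_motion <- f_mot
  state
}

#' Run the krill herd optimizer
#'
#' Minimises `fitness_fn` over the box `[lower, upper]^D`. The incumbent
#' best fitness per iteration is recorded and is non-increasing.
#'
#' @param fitness_fn Function mapping a length-`D` vector to a finite value.
#' @param config A [kha_config()].
#' @param init_position Optional position seeded as the first krill (e.g. a
#'   known default configuration in hyperparameter tuning).
#' @return A list of class `kha_result`: `best_position`, `best_fitness`,
#'   `trace` (tibble `iteration`, `best_fitness`), `state`.
#' @export
#' @examples
#' sphere <- function(x) sum(x^2)
#' res <- kha_optimize(sphere, kha_config(dim = 3, lower = -1, upper = 1,
#'                                        max_iterations = 30, seed = 1))
#' res$best_fitness
kha_optimize <- function(fitness_fn, config, init_position = NULL) {
  set.seed(derive_seed(config$seed, 5L))
  range <- config$upper - config$lower
  pos <- matrix(runif(config$n_krill * config$dim), config$n_krill, config$dim)
  pos <- sweep(sweep(pos, 2, range, "*"), 2, config$lower, "+")
  if (!is.null(init_position)) {
    if (length(init_position) != config$dim) stop_shape("`init_position` has wrong length.")
    pos[1, ] <- clamp(init_position, config$lower, config$upper)
  }
  fit <- apply(pos, 1, fitness_fn)
  if (any(!is.finite(fit))) stop_numeric("Fitness function returned a non-finite value.")
  best <- which.min(fit)
  state <- list(
    positions = pos, fitness = fit,
    n_motion = matrix(0, config$n_krill, config$dim),
    f_motion = matrix(0, config$n_krill, config$dim),
    best_position = pos[best, ], best_fitness = fit[best]
  )
  trace <- numeric(config$max_iterations)
  trace_positions <- matrix(NA_real_, config$max_iterations, config$dim)
  for (i in seq_len(config$max_iterations)) {
    state <- kha_step(state, i, config, fitness_fn)
    trace[i] <- state$best_fitness
    trace_positions[i, ] <- state$best_position
  }
  structure(
    list(
      best_position = state$best_position,
      best_fitness = state$best_fitness,
      trace = tibble::tibble(iteration = seq_len(config$max_iterations),
                             best_fitness = trace),
      trace_positions = trace_positions,
      state = state, config = config
    ),
    class = "kha_result"
  )
}

#' Percent classification error rate
#'
#' `100 * misclassified / total`, the fitness minimised during
#' hyperparameter tuning.
#'
#' @param predicted,actual Equal-length label vectors.
#' @return Percent error in `[0, 100]`.
#' @export
#' @examples
#' error_rate_fitness(c(0, 1, 1), c(0, 1, 0))  # 33.33...
error_rate_fitness <- function(predicted, actual) {
  if (length(predicted) != length(actual)) {
    stop_shape("`predicted` and `actual` must have equal length.")
  }
  if (length(actual) < 1) stop_shape("Need at least one sample.")
  100 * sum(predicted != actual) / length(actual)
}

#' Define a hyperparameter search space
#'
#' Each entry maps one coordinate of the unit hypercube searched by the
#' krill herd onto a [dcsae_config()] field, linearly or log-linearly, with
#' optional rounding to integers (half-up).
#'
#' @param ... Named lists `list(low =, high =, scale = "linear"|"log",
#'   kind = "real"|"integer")`; the names must be `dcsae_config` fields.
#' @return A tibble of class `hyperparam_space`.
#' @export
#' @examples
#' hyperparam_space(learning_rate = list(low = 1e-4, high = 1e-1, scale = "log"))
hyperparam_space <- function(...) {
  entries <- list(...)
  if (length(entries) == 0) stop_config("The space needs at least one entry.")
  if (is.null(names(entries)) || any(names(entries) == "")) {
    stop_config("Every space entry must be named.")
  }
  rows <- purrr::imap(entries, function(e, name) {
    scale <- e$scale %||% "linear"
    kind <- e$kind %||% "real"
    if (!scale %in% c("linear", "log")) stop_config("`scale` must be linear or log.")
    if (!kind %in% c("real", "integer")) stop_config("`kind` must be real or integer.")
    if (!is_scalar_number(e$low) || !is_scalar_number(e$high) || e$low > e$high) {
      stop_config(sprintf("Invalid bounds for '%s'.", name))
    }
    if (scale == "log" && e$low <= 0) stop_config("Log-scale bounds must be positive.")
    tibble::tibble(name = name, low = e$low, high = e$high,
                   scale = scale, kind = kind)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("hyperparam_space", class(out))
  out
}

#' Decode a unit-hypercube position into hyperparameter values
#'
#' @param space A [hyperparam_space()].
#' @param position Numeric vector in `[0, 1]^D`, one coordinate per entry.
#' @return Named list of decoded values, each within `[low, high]`.
#' @export
decode_hyperparams <- function(space, position) {
  if (length(position) != nrow(space)) stop_shape("Position length must match the space.")
  position <- clamp(position, 0, 1)
  vals <- purrr::pmap(list(space$low, space$high, space$scale, space$kind,
                           position),
                      function(low, high, scale, kind, u) {
    v <- if (scale == "log") exp(log(low) + u * (log(high) - log(low)))
         else low + u * (high - low)
    if (kind == "integer") v <- clamp(floor(v + 0.5), low, high)
    v
  })
  setNames(vals, space$name)
}

# Inverse of decode_hyperparams for seeding the swarm at a known config.
encode_hyperparams <- function(space, values) {
  vapply(seq_len(nrow(space)), function(i) {
    v <- values[[space$name[i]]]
    if (is.null(v)) return(0.5)
    if (space$low[i] == space$high[i]) return(0.5)
    u <- if (space$scale[i] == "log") {
      (log(v) - log(space$low[i])) / (log(space$high[i]) - log(space$low[i]))
    } else {
      (v - space$low[i]) / (space$high[i] - space$low[i])
    }
    clamp(u, 0, 1)
  }, numeric(1))
}

#' Default DCSAE tuning space
#'
#' Learning rate, reconstruction weight and sparsity weights on a log scale,
#' sparsity targets linear, and the first hidden width of the feature-view
#' encoder as an integer.
#'
#' @return A [hyperparam_space()].
#' @export
default_tuning_space <- function() {
  hyperparam_space(
    learning_rate = list(low = 1e-4, high = 1e-1, scale = "log"),
    recon_weight = list(low = 1e-3, high = 10, scale = "log"),
    sparsity_weight_f = list(low = 1e-4, high = 1, scale = "log"),
    sparsity_target_f = list(low = 0.01, high = 0.5),
    hidden1_f = list(low = 8, high = 64, kind = "integer")
  )
}

apply_hyperparams <- function(base, values) {
  for (name in names(values)) {
    if (name == "hidden1_f") {
      base$hidden_sizes_f[1] <- as.integer(values[[name]])
    } else if (name %in% names(base)) {
      base[[name]] <- values[[name]]
    } else {
      stop_config(sprintf("Unknown hyperparameter '%s'.", name))
    }
  }
  base
}

#' Tune DCSAE hyperparameters with the krill herd
#'
#' Splits off a stratified validation fraction, then runs the krill herd
#' over the unit hypercube: each krill decodes to a [dcsae_config()], a
#' model is trained on the training split with a reduced epoch budget, and
#' the fitness is the percent validation error ([error_rate_fitness()]). A
#' krill whose training diverges is assigned the worst fitness (100) and the
#' run continues. The swarm is warm-started with the base configuration, so
#' the returned configuration never scores worse than the base on the same
#' split. Retrain the winner at the full epoch budget afterwards.
#'
#' @param data Feature table with a label column.
#' @param label_column Name of the label column.
#' @param space A [hyperparam_space()]; default [default_tuning_space()].
#' @param kha A [kha_config()] with `dim = nrow(space)`; `NULL` builds a
#'   small default swarm.
#' @param base A [dcsae_config()] supplying every untuned field.
#' @param valid_fraction Stratified held-out fraction for the fitness.
#' @param inner_epochs Reduced epoch budget used inside the tuner.
#' @param seed Seed for the split (the swarm uses `kha$seed`).
#' @return A list of class `kha_tuning`: `best_config`, `best_values`,
#'   `best_error` (percent), `baseline_error`, `trace` (tibble with decoded
#'   parameters per iteration), `space`.
#' @export
tune_dcsae <- function(data, label_column = "y", space = default_tuning_space(),
                       kha = NULL, base = dcsae_config(),
                       valid_fraction = 0.25, inner_epochs = 10, seed = 1) {
  parts <- split_table(data, label_column)
  if (length(unique(parts$y)) < 2) stop_label("Tuning needs at least two classes.")
  folds <- stratified_folds(parts$y, round(1 / valid_fraction), seed)
  valid <- folds == 1L
  train_tbl <- data[!valid, , drop = FALSE]
  valid_tbl <- data[valid, , drop = FALSE]
  kha <- kha %||% kha_config(dim = nrow(space), n_krill = 8,
                             max_iterations = 10, seed = seed)
  if (kha$dim != nrow(space)) stop_shape("`kha$dim` must equal the number of space entries.")

  eval_config <- function(values) {
    config <- apply_hyperparams(base, values)
    config$epochs <- as.integer(inner_epochs)
    config$seed <- base$seed
    tryCatch({
      fit <- train_dcsae(train_tbl, label_column, config = config)
      pred <- predict(fit, valid_tbl)
      error_rate_fitness(pred$.pred_class, valid_tbl[[label_column]])
    }, error = function(e) 100)
  }
  cache <- new.env(parent = emptyenv())
  fitness_fn <- function(u) {
    values <- decode_hyperparams(space, u)
    key <- paste(signif(unlist(values), 10), collapse = "|")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- eval_config(values)
    cache[[key]] <- val
    val
  }

  base_u <- encode_hyperparams(space, base)
  baseline_error <- fitness_fn(base_u)
  res <- kha_optimize(fitness_fn, kha, init_position = base_u)
  best_values <- decode_hyperparams(space, res$best_position)
  best_config <- apply_hyperparams(base, best_values)

  decoded <- purrr::map(res$trace$iteration, function(i) {
    tibble::as_tibble(decode_hyperparams(space, res$trace_positions[i, ]))
  })
  trace <- dplyr::bind_cols(res$trace, dplyr::bind_rows(decoded))
  structure(
    list(best_config = best_config, best_values = best_values,
         best_error = res$best_fitness, baseline_error = baseline_error,
         trace = trace, space = space, kha = kha),
    class = "kha_tuning"
  )
}
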