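#' Coyote optimization configuration
#'
#' Settings for the coyote optimization algorithm (COA), a population
#' metaheuristic that organises candidate solutions into packs. Each pack
#' evolves through alpha-guided social updates, a cultural tendency (the
#' componentwise median of the pack), and birth/death replacement by pups.
#'
#' The scatter and association probabilities default to `Prs = 1/D` and
#' `Pra = (1 - Prs)/2`, where `D` is the problem dimension.
#'
#' @param dim Problem dimension `D`.
#' @param n_packs Number of packs.
#' @param coyotes_per_pack Coyotes per pack `Nc` (at most 14).
#' @param max_iterations Number of sweeps over the population.
#' @param lower,upper Bounds; scalars are recycled to length `dim`.
#' @param scatter_probability `Prs`; default `1/dim`.
#' @param association_probability `Pra`; default `(1 - Prs)/2`.
#' @param seed Integer seed controlling all random draws.
#' @return A list of class `coa_config`.
#' @export
coa_config <- function(dim,
                       n_packs = 4,
                       coyotes_per_pack = 10,
                       max_iterations = 50,
                       lower = 0,
                       upper = 1,
                       scatter_probability = NULL,
                       association_probability = NULL,
                       seed = 1) {
  if (!is_scalar_number(dim) || dim < 1) stop_config("`dim` must be a positive integer.")
  if (coyotes_per_pack < 2 || coyotes_per_pack > 14) {
    stop_config("`coyotes_per_pack` must be between 2 and 14.")
  }
  if (n_packs < 1 || max_iterations < 1) {
    stop_config("`n_packs` and `max_iterations` must be positive.")
  }
  lower <- rep_len(lower, dim)
  upper <- rep_len(upper, dim)
  if (any(lower > upper)) stop_config("`lower` must not exceed `upper`.")
  prs <- scatter_probability %||% (1 / dim)
  pra <- association_probability %||% ((1 - prs) / 2)
  if (prs <= 0 || prs > 1 || pra < 0 || pra >= 1) {
    stop_config("Invalid scatter/association probabilities.")
  }
  structure(
    list(
      dim = as.integer(dim), n_packs = as.integer(n_packs),
      coyotes_per_pack = as.integer(coyotes_per_pack),
      max_iterations = as.integer(max_iterations),
      lower = lower, upper = upper,
      scatter_probability = prs, association_probability = pra,
      seed = as.integer(seed)
    ),
    class = "coa_config"
  )
}

#' Initialise a coyote population
#'
#' Draws every coordinate as `lb + r * (ub - lb)` with `r` uniform in
#' `[0, 1]`, evaluates all costs and records each pack's alpha (lowest-cost
#' coyote). Random draws use the config seed, so identical configs give
#' identical populations.
#'
#' @param cost_fn Function mapping a length-`dim` numeric vector to a finite
#'   cost (lower is better).
#' @param config A [coa_config()].
#' @return A list of class `coa_population` with elements `positions`
#'   (list of `Nc x D` matrices, one per pack), `costs` (list of numeric
#'   vectors), `alpha_index` (integer per pack) and `iteration`.
#' @export
init_population <- function(cost_fn, config) {
  set.seed(derive_seed(config$seed, 1L))
  positions <- vector("list", config$n_packs)
  costs <- vector("list", config$n_packs)
  alpha_index <- integer(config$n_packs)
  range <- config$upper - config$lower
  for (p in seq_len(config$n_packs)) {
    r <- matrix(runif(config$coyotes_per_pack * config$dim),
                nrow = config$coyotes_per_pack)
    pos <- sweep(sweep(r, 2, range, "*"), 2, config$lower, "+")
    cost <- apply(pos, 1, cost_fn)
    if (any(!is.finite(cost))) stop_numeric("Cost function returned a non-finite value.")
    positions[[p]] <- pos
    costs[[p]] <- cost
    alpha_index[p] <- which.min(cost)
  }
  structure(
    list(positions = positions, costs = costs,
         alpha_index = alpha_index, iteration = 0L),
    class = "coa_population"
  )
}

#' Cultural (social) tendency of a pack
#'
#' The componentwise median of the pack's social states: the middle ranked
#' value for an odd pack size, the mean of the two middle ranked values for
#' an even pack size.
#'
#' @param pack_positions `Nc x D` matrix of coyote positions.
#' @return Length-`D` numeric vector.
#' @export
social_tendency <- function(pack_positions) {
  pack_positions <- as.matrix(pack_positions)
  nc <- nrow(pack_positions)
  if (nc < 1) stop_shape("Pack must contain at least one coyote.")
  apply(pack_positions, 2, function(col) {
    s <- sort(col)
    if (nc %% 2 == 1) s[(nc + 1) / 2] else (s[nc / 2] + s[nc / 2 + 1]) / 2
  })
}

#' Social update of a single coyote
#'
#' Proposes `X + r1 * (alpha - X_r1) + r2 * (tendency - X_r2)` with `r1`,
#' `r2` uniform in `[0, 1]` and `X_r1`, `X_r2` random pack members, clips the
#' candidate to the bounds, and accepts it only if its cost is strictly
#' lower (greedy acceptance), so a coyote's cost never increases.
#'
#' @param position Current length-`D` position.
#' @param cost Current cost.
#' @param alpha Position of the pack's alpha coyote.
#' @param tendency Pack tendency from [social_tendency()].
#' @param pack_positions `Nc x D` matrix the random peers are drawn from.
#' @param cost_fn Cost function.
#' @param lower,upper Bounds.
#' @param r1,r2 Optional fixed scalars replacing the uniform draws (useful
#'   for testing); `NULL` draws them from the current RNG stream.
#' @return List with updated `position` and `cost`.
#' @export
update_coyote <- function(position, cost, alpha, tendency, pack_positions,
                          cost_fn, lower, upper, r1 = NULL, r2 = NULL) {
  nc <- nrow(pack_positions)
  r1 <- r1 %||% runif(1)
  r2 <- r2 %||% runif(1)
  peer1 <- pack_positions[sample.int(nc, 1), ]
  peer2 <- pack_positions[sample.int(nc, 1), ]
  candidate <- clamp(position + r1 * (alpha - peer1) + r2 * (tendency - peer2),
                     lower, upper)
  new_cost <- cost_fn(candidate)
  if (!is.finite(new_cost)) stop_numeric("Cost function returned a non-finite value.")
  if (new_cost < cost) list(position = candidate, cost = new_cost)
  else list(position = position, cost = cost)
}

#' Birth of a pup from two pack parents
#'
#' Chooses two distinct parents and two distinct guaranteed dimensions
#' `i1`, `i2`. Per dimension `j` with a fresh uniform draw `r_j`: inherit
#' from parent 1 if `r_j >= Prs + Pra` or `j == i1`; from parent 2 if
#' `r_j < Prs` or `j == i2`; otherwise take a fresh uniform value within the
#' bounds (scatter).
#'
#' @param pack_positions `Nc x D` matrix (`Nc >= 2`).
#' @param config A [coa_config()].
#' @return Length-`D` pup position.
#' @export
birth_pup <- function(pack_positions, config) {
  nc <- nrow(pack_positions)
  if (nc < 2) stop_config("Pup birth needs at least two coyotes in the pack.")
  d <- config$dim
  parents <- sample.int(nc, 2)
  dims <- if (d >= 2) sample.int(d, 2) else c(1L, 1L)
  r <- runif(d)
  fresh <- config$lower + runif(d) * (config$upper - config$lower)
  pup <- fresh
  from1 <- r >= (config$scatter_probability + config$association_probability)
  from2 <- r < config$scatter_probability
  from1[dims[1]] <- TRUE
  from2[dims[1]] <- FALSE
  from2[dims[2]] <- TRUE
  from1[dims[2]] <- FALSE
  pup[from1] <- pack_positions[parents[1], from1]
  pup[from2 & !from1] <- pack_positions[parents[2], from2 & !from1]
  pup
}

#' Replace the worst pack member with a better pup
#'
#' The pup replaces the highest-cost coyote only when the pup's cost is
#' strictly lower, so the pack's best cost never increases.
#'
#' @param pack_positions `Nc x D` matrix.
#' @param pack_costs Length-`Nc` cost vector.
#' @param pup Length-`D` pup position.
#' @param pup_cost Pup cost.
#' @return List with `positions`, `costs` and logical `replaced`.
#' @export
replace_with_pup <- function(pack_positions, pack_costs, pup, pup_cost) {
  worst <- which.max(pack_costs)
  if (pup_cost < pack_costs[worst]) {
    pack_positions[worst, ] <- pup
    pack_costs[worst] <- pup_cost
    list(positions = pack_positions, costs = pack_costs, replaced = TRUE)
  } else {
    list(positions = pack_positions, costs = pack_costs, replaced = FALSE)
  }
}

#' Run the coyote optimization algorithm
#'
#' Minimises `cost_fn` over the box `[lower, upper]^D`. Each iteration
#' sweeps every pack: social updates against the pack alpha and the cultural
#' tendency, then one pup birth with worst-member replacement. The incumbent
#' best cost per iteration is recorded (non-increasing by construction).
#'
#' @inheritParams init_population
#' @return A list of class `coa_result`: `best_position`, `best_cost`,
#'   `trace` (tibble `iteration`, `best_cost`), and the final `population`.
#' @export
#' @examples
#' sphere <- function(x) sum(x^2)
#' res <- coa_optimize(sphere, coa_config(dim = 3, lower = -1, upper = 1,
#'                                        max_iterations = 20, seed = 1))
#' res$best_cost
coa_optimize <- function(cost_fn, config) {
  pop <- init_population(cost_fn, config)
  set.seed(derive_seed(config$seed, 2L))
  best_cost <- Inf
  best_position <- NULL
  for (p in seq_len(config$n_packs)) {
    i <- which.min(pop$costs[[p]])
    if (pop$costs[[p]][i] < best_cost) {
      best_cost <- pop$costs[[p]][i]
      best_position <- pop$positions[[p]][i, ]
    }
  }
  trace <- numeric(config$max_iterations)
  for (t in seq_len(config$max_iterations)) {
    for (p in seq_len(config$n_packs)) {
      pos <- pop$positions[[p]]
      cst <- pop$costs[[p]]
      alpha <- pos[which.min(cst), ]
      tendency <- social_tendency(pos)
      for (c in seq_len(config$coyotes_per_pack)) {
        upd <- update_coyote(pos[c, ], cst[c], alpha, tendency, pos,
                             cost_fn, config$lower, config$upper)
        pos[c, ] <- upd$position
        cst[c] <- upd$cost
      }
      pup <- birth_pup(pos, config)
      pup_cost <- cost_fn(pup)
      if (!is.finite(pup_cost)) stop_numeric("Cost function returned a non-finite value.")
      rep <- replace_with_pup(pos, cst, pup, pup_cost)
      pop$positions[[p]] <- rep$positions
      pop$costs[[p]] <- rep$costs
      pop$alpha_index[p] <- which.min(rep$costs)
      i <- which.min(rep$costs)
      if (rep$costs[i] < best_cost) {
        best_cost <- rep$costs[i]
        best_position <- rep$positions[i, ]
      }
    }
    pop$iteration <- t
    trace[t] <- best_cost
  }
  structure(
    list(
      best_position = best_position, best_cost = best_cost,
      trace = tibble::tibble(iteration = seq_len(config$max_iterations),
                             best_cost = trace),
      population = pop, config = config
    ),
    class = "coa_result"
  )
}

#' Feature-subset fitness: weighted error rate plus subset size
#'
#' `fitness = alpha * error + (1 - alpha) * n_selected / n_total`, balancing
#' the wrapped classifier's error rate against the fraction of features
#' kept. With the default `alpha = 0.99` classification error dominates and
#' subset size only breaks near-ties.
#'
#' @param mask Logical vector of selected features.
#' @param error_rate Classifier error rate in `[0, 1]` for that mask.
#' @param alpha_weight Weight on the error term, in `[0, 1]`.
#' @return Scalar fitness (lower is better).
#' @export
fs_fitness <- function(mask, error_rate, alpha_weight = 0.99) {
  if (!is.logical(mask) || length(mask) < 1) stop_shape("`mask` must be a logical vector.")
  if (!is_scalar_number(error_rate) || error_rate < 0 || error_rate > 1) {
    abort("Error estimator must return a value in [0, 1].",
          class = "seizecca_error_contract")
  }
  if (!is_scalar_number(alpha_weight) || alpha_weight < 0 || alpha_weight > 1) {
    stop_config("`alpha_weight` must be in [0, 1].")
  }
  alpha_weight * error_rate + (1 - alpha_weight) * sum(mask) / length(mask)
}

#' Wrapper feature selection with the coyote optimizer
#'
#' Runs COA over continuous positions in `[0, 1]^D`; every position is
#' binarised (coordinate `> threshold` selects the feature) before the
#' fitness of [fs_fitness()] is evaluated with a cross-validated classifier
#' error. An all-false mask is assigned the worst error (1) without calling
#' the estimator. Fitness values are cached per mask, since the continuous
#' search revisits masks frequently.
#'
#' @param data Normalized feature table (tibble) with a label column.
#' @param label_column Name of the label column.
#' @param coa A [coa_config()] with `dim` equal to the number of features;
#'   `NULL` builds a default config from `seed`.
#' @param alpha_weight Error-rate weight of [fs_fitness()]; default 0.99.
#' @param threshold Binarisation cut on the continuous positions.
#' @param error_estimator Function `(x, y) -> error in [0, 1]` evaluated on
#'   the masked feature matrix. Default: stratified 3-fold CV error of a
#'   regularised linear discriminant classifier (ridge on the pooled
#'   within-class covariance, training-frequency priors).
#' @param seed Seed used when `coa` is `NULL` and by the error estimator.
#' @return A list of class `coa_selection`: logical `mask`, `features`
#'   (selected names), `n_selected`, `best_cost`, `trace`, `alpha_weight`,
#'   `threshold`, `config`.
#' @export
select_features <- function(data, label_column = "y", coa = NULL,
                            alpha_weight = 0.99, threshold = 0.5,
                            error_estimator = NULL, seed = 1) {
  parts <- split_table(data, label_column)
  if (length(unique(parts$y)) < 2) {
    stop_label("Feature selection needs at least two classes in the labels.")
  }
  d <- ncol(parts$x)
  coa <- coa %||% coa_config(dim = d, lower = 0, upper = 1, seed = seed)
  if (coa$dim != d) stop_shape("`coa$dim` must equal the number of features.")
  error_estimator <- error_estimator %||%
    function(x, y) linear_cv_error(x, y, k = 3, seed = seed)

  cache <- new.env(parent = emptyenv())
  cost_fn <- function(position) {
    mask <- position > threshold
    key <- rawToChar(as.raw(as.integer(mask) + 48L))
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    err <- if (!any(mask)) 1 else {
      e <- error_estimator(parts$x[, mask, drop = FALSE], parts$y)
      if (!is_scalar_number(e) || e < 0 || e > 1) {
        abort("Error estimator must return a value in [0, 1].",
              class = "seizecca_error_contract")
      }
      e
    }
    val <- fs_fitness(mask, err, alpha_weight)
    cache[[key]] <- val
    val
  }

  res <- coa_optimize(cost_fn, coa)
  mask <- res$best_position > threshold
  structure(
    list(
      mask = mask,
      features = parts$features[mask],
      n_selected = sum(mask),
      best_cost = res$best_cost,
      trace = res$trace,
      alpha_weight = alpha_weight,
      threshold = threshold,
      config = coa
    ),
    class = "coa_selection"
  )
}

#' Persist a feature mask as text plus a JSON sidecar
#'
#' Writes the selected feature names one per line, and a `.json` sidecar
#' recording the best cost, weights, seed and iteration budget.
#'
#' @param selection A `coa_selection` from [select_features()].
#' @param path Output path for the name list; the sidecar is `path` with a
#'   `.json` extension appended.
#' @return `path`, invisibly.
#' @export
write_feature_mask <- function(selection, path) {
  writeLines(selection$features, path)
  sidecar <- list(
    n_selected = selection$n_selected,
    best_cost = selection$best_cost,
    alpha = selection$alpha_weight,
    beta = 1 - selection$alpha_weight,
    threshold = selection$threshold,
    seed = selection$config$seed,
    iterations = selection$config$max_iterations
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
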