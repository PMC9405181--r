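sphere <- function(x) sum(x^2)

test_that("the inertia schedule is linear from 0.9 to 0.1", {
  cfg <- kha_config(dim = 2, max_iterations = 100)
  expect_equal(kha_inertia(0, cfg), 0.9)
  expect_equal(kha_inertia(50, cfg), 0.5)
  expect_equal(kha_inertia(100, cfg), 0.1)
})

test_that("induced motion vanishes with zero inertia and no attraction", {
  cfg <- kha_config(dim = 3, n_krill = 4, max_iterations = 10,
                    inertia_start = 0, inertia_end = 0, lower = -1, upper = 1)
  pos <- matrix(0.5, 4, 3)  # all krill identical: K_hat and X_hat are zero
  fit <- rep(2, 4)
  n <- induced_motion(pos, fit, matrix(0, 4, 3), pos[1, ], 2, 5, cfg)
  expect_equal(n, matrix(0, 4, 3))
})

test_that("foraging motion vanishes at zero speed and inertia", {
  cfg <- kha_config(dim = 2, n_krill = 3, max_iterations = 10,
                    inertia_start = 0, inertia_end = 0, lower = 0, upper = 1)
  cfg$foraging_speed <- 0  # constructor requires > 0; exercise the formula
  pos <- matrix(runif(6), 3, 2)
  fit <- c(1, 2, 3)
  f <- foraging_motion(pos, fit, matrix(0, 3, 2), food_position(pos, fit),
                       1.5, pos[1, ], 1, 5, cfg)
  expect_equal(f, matrix(0, 3, 2))
})

test_that("the food position is the inverse-fitness-weighted centroid", {
  pos <- matrix(c(0, 1), 2, 1)
  expect_equal(food_position(pos, c(1, 3)), 0.25, tolerance = 1e-6)
  same <- matrix(0.7, 5, 3)
  expect_equal(food_position(same, runif(5, 1, 2)), rep(0.7, 3))
})

test_that("diffusion decays linearly to exactly zero and stays bounded", {
  cfg <- kha_config(dim = 4, n_krill = 6, max_iterations = 50, lower = 0, upper = 1)
  set.seed(1)
  d_mid <- physical_diffusion(6, 25, cfg)
  expect_true(all(abs(d_mid) <= cfg$diffusion_max))
  expect_identical(physical_diffusion(6, 50, cfg), matrix(0, 6, 4))
  set.seed(9); a <- physical_diffusion(6, 10, cfg)
  set.seed(9); b <- physical_diffusion(6, 10, cfg)
  expect_identical(a, b)
})

test_that("a step with a null motion field leaves positions unchanged", {
  cfg <- kha_config(dim = 2, n_krill = 3, max_iterations = 10,
                    inertia_start = 0, inertia_end = 0, lower = -1, upper = 1)
  cfg$n_max <- 0
  cfg$foraging_speed <- 0
  pos <- matrix(runif(6, -1, 1), 3, 2)
  state <- list(positions = pos, fitness = apply(pos, 1, sphere),
                n_motion = matrix(0, 3, 2), f_motion = matrix(0, 3, 2),
                best_position = pos[1, ], best_fitness = sphere(pos[1, ]))
  # final iteration: diffusion is exactly zero too
  out <- kha_step(state, 10, cfg, sphere)
  expect_equal(out$positions, pos)
})

test_that("the incumbent never worsens and positions stay in bounds", {
  cfg <- kha_config(dim = 3, n_krill = 10, max_iterations = 40,
                    lower = -1, upper = 1, seed = 8)
  res <- kha_optimize(sphere, cfg)
  expect_true(all(diff(res$trace$best_fitness) <= 0))
  expect_true(all(res$state$positions >= -1 & res$state$positions <= 1))
  expect_lt(res$best_fitness, 0.05)
  res2 <- kha_optimize(sphere, cfg)
  expect_identical(res$trace, res2$trace)
})

test_that("later iterations dominate earlier ones on a convex quadratic", {
  quad <- function(x) sum((x - 0.3)^2)
  at10 <- at100 <- numeric(10)
  for (s in 1:10) {
    res <- kha_optimize(quad, kha_config(dim = 2, n_krill = 12,
                                         max_iterations = 100,
                                         lower = -1, upper = 1, seed = s))
    at10[s] <- res$trace$best_fitness[10]
    at100[s] <- res$trace$best_fitness[100]
  }
  expect_lt(mean(at100), mean(at10))
})

test_that("percent error rate follows the misclassification count", {
  expect_identical(error_rate_fitness(c(rep(0, 97), rep(1, 3)), rep(0, 100)), 3)
  expect_identical(error_rate_fitness(1:5, 1:5), 0)
  expect_identical(error_rate_fitness(rep(1, 4), rep(0, 4)), 100)
  expect_error(error_rate_fitness(1:3, 1:4), class = "seizecca_error_shape")
})

test_that("hyperparameter decoding respects scales, bounds and rounding", {
  space <- hyperparam_space(
    learning_rate = list(low = 1e-4, high = 1e-1, scale = "log"),
    hidden1_f = list(low = 8, high = 64, kind = "integer"),
    sparsity_target_f = list(low = 0.1, high = 0.5)
  )
  vals <- decode_hyperparams(space, c(0.5, 0.5, 0))
  expect_equal(vals$learning_rate, sqrt(1e-4 * 1e-1), tolerance = 1e-12)
  expect_equal(vals$hidden1_f, 36)  # 36 = round half-up of 8 + 0.5 * 56
  expect_equal(vals$sparsity_target_f, 0.1)
  expect_equal(decode_hyperparams(space, c(0, 0, 1))$learning_rate, 1e-4)
  expect_equal(decode_hyperparams(space, c(1, 1, 1))$hidden1_f, 64)

  # encoding inverts decoding
  u <- seizecca:::encode_hyperparams(space, vals)
  expect_equal(unname(u), c(0.5, 0.5, 0), tolerance = 1e-9)
  expect_error(decode_hyperparams(space, c(0.5, 0.5)), class = "seizecca_error_shape")
  expect_error(hyperparam_space(lr = list(low = 2, high = 1)),
               class = "seizecca_error_config")
})

test_that("a degenerate one-point space returns exactly that value", {
  tbl <- easy_binary_table(n_per_class = 30, n_features = 6, seed = 12)
  norm <- apply_minmax(tbl, fit_minmax(tbl))
  space <- hyperparam_space(learning_rate = list(low = 0.02, high = 0.02))
  tuned <- tune_dcsae(
    norm, space = space,
    kha = kha_config(dim = 1, n_krill = 3, max_iterations = 2, seed = 4),
    base = dcsae_config(hidden_sizes_f = 4, hidden_sizes_g = 3, epochs = 2, seed = 4),
    inner_epochs = 2, seed = 4
  )
  expect_equal(tuned$best_config$learning_rate, 0.02)
  expect_true(all(diff(tuned$trace$best_fitness) <= 0))
  expect_lte(tuned$best_error, tuned$baseline_error)
})

test_that("a diverging krill is assigned the worst fitness and the run continues", {
  tbl <- easy_binary_table(n_per_class = 20, n_features = 5, seed = 13)
  norm <- apply_minmax(tbl, fit_minmax(tbl))
  # linear encoders with momentum diverge at these rates; the tuner must
  # survive the resulting training errors
  space <- hyperparam_space(learning_rate = list(low = 1e3, high = 1e6, scale = "log"))
  tuned <- tune_dcsae(
    norm, space = space,
    kha = kha_config(dim = 1, n_krill = 3, max_iterations = 2, seed = 5),
    base = dcsae_config(hidden_sizes_f = 4, hidden_sizes_g = 3, epochs = 10,
                        momentum = 0.9, activation = "linear", seed = 5),
    inner_epochs = 10, seed = 5
  )
  expect_equal(tuned$best_error, 100)
})
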