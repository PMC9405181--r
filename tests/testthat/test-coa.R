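sphere <- function(x) sum(x^2)

test_that("population initialisation respects bounds, zero ranges and seeds", {
  cfg <- coa_config(dim = 4, n_packs = 2, coyotes_per_pack = 5,
                    lower = c(0, 0, 2, 2), upper = c(0, 0, 2, 2), seed = 3)
  pop <- init_population(sphere, cfg)
  for (p in 1:2) {
    expect_true(all(pop$positions[[p]] == matrix(c(0, 0, 2, 2), 5, 4, byrow = TRUE)))
  }

  cfg2 <- coa_config(dim = 6, n_packs = 3, coyotes_per_pack = 7,
                     lower = -2, upper = 3, seed = 11)
  pop2 <- init_population(sphere, cfg2)
  for (p in 1:3) {
    expect_true(all(pop2$positions[[p]] >= -2 & pop2$positions[[p]] <= 3))
    expect_equal(pop2$alpha_index[p], which.min(pop2$costs[[p]]))
  }
  pop3 <- init_population(sphere, cfg2)
  expect_identical(pop2$positions, pop3$positions)
})

test_that("social tendency is the componentwise ranked median", {
  expect_equal(social_tendency(matrix(c(1, 2, 9))), 2)
  expect_equal(social_tendency(matrix(c(1, 3))), 2)
  one <- matrix(c(0.3, 0.8, 0.1), 1, 3)
  expect_equal(social_tendency(rbind(one, one, one, one)), drop(one))
  set.seed(5)
  for (nc in c(2, 3, 6, 7)) {
    m <- matrix(rnorm(nc * 4), nc, 4)
    expect_equal(social_tendency(m), apply(m, 2, median))
  }
})

test_that("social update is greedy: accepted only when strictly better", {
  pack <- matrix(runif(20), 5, 4)
  pos <- pack[1, ]
  # r1 = r2 = 0 leaves the position unchanged, so the cost cannot improve
  set.seed(1)
  upd <- update_coyote(pos, sphere(pos), pack[2, ], social_tendency(pack),
                       pack, sphere, rep(0, 4), rep(1, 4), r1 = 0, r2 = 0)
  expect_equal(upd$position, pos)
  expect_equal(upd$cost, sphere(pos))

  # a candidate that can only be worse is rejected
  upd2 <- update_coyote(pos, 0, pack[2, ], social_tendency(pack), pack,
                        function(x) 10, rep(0, 4), rep(1, 4))
  expect_equal(upd2$position, pos)
  expect_equal(upd2$cost, 0)

  # repeated greedy sweeps never increase any coyote's cost
  set.seed(7)
  costs <- apply(pack, 1, sphere)
  for (sweep in 1:20) {
    alpha <- pack[which.min(costs), ]
    tend <- social_tendency(pack)
    for (c in 1:5) {
      old <- costs[c]
      upd <- update_coyote(pack[c, ], costs[c], alpha, tend, pack, sphere,
                           rep(0, 4), rep(1, 4))
      pack[c, ] <- upd$position
      costs[c] <- upd$cost
      expect_lte(costs[c], old)
    }
  }
})

test_that("pup birth follows the scatter/association branch logic", {
  # association dominant: every gene comes from a parent, both forced
  # dimensions included, no fresh random values
  cfg <- coa_config(dim = 40, coyotes_per_pack = 2, lower = 0, upper = 1,
                    scatter_probability = 0.9989, association_probability = 0.001,
                    seed = 2)
  pack <- rbind(rep(0.2, 40), rep(0.8, 40))
  set.seed(21)
  for (i in 1:10) {
    pup <- birth_pup(pack, cfg)
    expect_true(all(pup %in% c(0.2, 0.8)))
    expect_true(any(pup == 0.2) && any(pup == 0.8))  # i1 and i2 are forced
  }

  # with a wide association band most genes are fresh uniform draws
  cfg2 <- coa_config(dim = 40, coyotes_per_pack = 2, lower = 0, upper = 1,
                     scatter_probability = 0.05, association_probability = 0.9,
                     seed = 2)
  set.seed(22)
  pup2 <- birth_pup(pack, cfg2)
  expect_gt(sum(!pup2 %in% c(0.2, 0.8)), 15)
  expect_true(all(pup2 >= 0 & pup2 <= 1))

  expect_error(birth_pup(pack[1, , drop = FALSE], cfg), class = "seizecca_error_config")
})

test_that("default scatter and association probabilities follow 1/D", {
  cfg <- coa_config(dim = 178)
  expect_equal(cfg$scatter_probability, 1 / 178)
  expect_equal(cfg$association_probability, (1 - 1 / 178) / 2)
  expect_equal(cfg$scatter_probability, 0.005618, tolerance = 1e-4)
  expect_equal(cfg$association_probability, 0.497191, tolerance = 1e-4)
})

test_that("pup replacement only ever improves the worst pack member", {
  pack <- matrix(c(0, 0, 1, 1, 2, 2), 3, 2, byrow = TRUE)
  costs <- c(0, 2, 8)
  rep1 <- replace_with_pup(pack, costs, c(0.5, 0.5), 0.5)
  expect_true(rep1$replaced)
  expect_equal(rep1$positions[3, ], c(0.5, 0.5))
  expect_equal(max(rep1$costs), 2)

  rep2 <- replace_with_pup(pack, costs, c(9, 9), 162)
  expect_false(rep2$replaced)
  expect_identical(rep2$positions, pack)
  # the best member is untouched either way
  expect_equal(min(rep1$costs), 0)
  expect_equal(min(rep2$costs), 0)
})

test_that("subset fitness combines error rate and subset size", {
  mask <- rep(c(TRUE, FALSE), c(89, 89))
  expect_equal(fs_fitness(mask, 0.1, alpha_weight = 0.99),
               0.99 * 0.1 + 0.01 * 0.5)
  expect_equal(fs_fitness(rep(FALSE, 10), 0, alpha_weight = 0.6), 0)
  expect_equal(fs_fitness(rep(TRUE, 10), 1, alpha_weight = 0.7), 1)
  expect_error(fs_fitness(mask, 1.2), class = "seizecca_error_contract")
})

test_that("optimizer keeps positions in bounds with a non-increasing trace", {
  cfg <- coa_config(dim = 5, n_packs = 3, coyotes_per_pack = 6,
                    max_iterations = 40, lower = -1, upper = 1, seed = 4)
  res <- coa_optimize(sphere, cfg)
  expect_true(all(diff(res$trace$best_cost) <= 0))
  expect_lt(res$best_cost, 0.05)
  for (p in seq_along(res$population$positions)) {
    expect_true(all(abs(res$population$positions[[p]]) <= 1))
  }
  res2 <- coa_optimize(sphere, cfg)
  expect_identical(res$trace, res2$trace)
  expect_identical(res$best_position, res2$best_position)
})

test_that("feature selection honours the fitness contract and determinism", {
  tbl <- easy_binary_table(n_per_class = 40, n_features = 10, seed = 5)
  norm <- apply_minmax(tbl, fit_minmax(tbl))
  cfg <- coa_config(dim = 10, n_packs = 2, coyotes_per_pack = 5,
                    max_iterations = 8, seed = 6)

  # alpha = 1 with a constant estimator: every mask is optimal and the
  # returned cost equals the constant
  sel <- select_features(norm, coa = cfg, alpha_weight = 1,
                         error_estimator = function(x, y) 0.25)
  expect_equal(sel$best_cost, 0.25)

  sel1 <- select_features(norm, coa = cfg, seed = 6)
  sel2 <- select_features(norm, coa = cfg, seed = 6)
  expect_identical(sel1$mask, sel2$mask)
  expect_identical(sel1$trace, sel2$trace)
  expect_true(all(diff(sel1$trace$best_cost) <= 0))
  expect_identical(sel1$features, paste0("X", which(sel1$mask)))

  expect_error(
    select_features(norm, coa = cfg, error_estimator = function(x, y) 1.5),
    class = "seizecca_error_contract"
  )
  onecls <- norm
  onecls$y <- 0L
  expect_error(select_features(onecls, coa = cfg), class = "seizecca_error_label")
})

test_that("selection artifacts round-trip through the text sidecar", {
  tbl <- easy_binary_table(n_per_class = 30, n_features = 8, seed = 2)
  norm <- apply_minmax(tbl, fit_minmax(tbl))
  sel <- select_features(norm, coa = coa_config(dim = 8, n_packs = 2,
                                                coyotes_per_pack = 4,
                                                max_iterations = 5, seed = 1))
  path <- withr::local_tempfile(fileext = ".txt")
  write_feature_mask(sel, path)
  expect_identical(readLines(path), sel$features)
  side <- jsonlite::fromJSON(paste0(path, ".json"))
  expect_equal(side$best_cost, sel$best_cost)
  expect_equal(side$alpha, 0.99)
  expect_equal(side$beta, 0.01)
})
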