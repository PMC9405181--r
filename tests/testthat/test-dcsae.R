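test_that("cca_layer matches the generalized-eigenproblem oracle", {
  set.seed(31)
  for (rep in 1:5) {
    h1 <- matrix(rnorm(60), 20, 3)
    h2 <- matrix(rnorm(60), 20, 3)
    res <- cca_layer(h1, h2, r_x = 1e-12, r_y = 1e-12, dims = 3)
    oracle <- oracle_cca_correlations(h1, h2)
    expect_equal(res$correlation, sum(oracle), tolerance = 1e-8)
    expect_equal(sort(res$singular_values, decreasing = TRUE),
                 sort(oracle, decreasing = TRUE), tolerance = 1e-8)
  }
})

test_that("whitening constraints hold at the returned directions", {
  set.seed(32)
  h1 <- matrix(rnorm(200), 50, 4)
  h2 <- matrix(rnorm(150), 50, 3)
  r <- 1e-4
  res <- cca_layer(h1, h2, r, r, dims = 3)
  h1c <- scale(h1, scale = FALSE)
  h2c <- scale(h2, scale = FALSE)
  s11 <- crossprod(h1c) / 50 + diag(r, 4)
  s22 <- crossprod(h2c) / 50 + diag(r, 3)
  expect_lt(max(abs(t(res$u) %*% s11 %*% res$u - diag(3))), 1e-6)
  expect_lt(max(abs(t(res$v) %*% s22 %*% res$v - diag(3))), 1e-6)
  # cross-orthogonality: U' S12 V is diagonal (the singular values)
  s12 <- crossprod(h1c, h2c) / 50
  cross <- t(res$u) %*% s12 %*% res$v
  expect_equal(cross, diag(res$singular_values), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("identical views are perfectly correlated; independent views are not", {
  set.seed(33)
  h <- matrix(rnorm(60), 20, 3)
  expect_equal(cca_layer(h, h, 1e-12, 1e-12, 3)$correlation, 3, tolerance = 1e-6)

  a <- matrix(rnorm(2e5), 1e5, 2)
  b <- matrix(rnorm(2e5), 1e5, 2)
  expect_lt(abs(cca_layer(a, b, 1e-6, 1e-6, 1)$correlation), 0.02)
})

test_that("cca correlation is invariant to invertible affine view transforms", {
  set.seed(34)
  h1 <- matrix(rnorm(150), 50, 3)
  h2 <- matrix(rnorm(150), 50, 3)
  base <- cca_layer(h1, h2, 1e-12, 1e-12, 3)$correlation
  amat <- matrix(c(2, 0.5, 0, -1, 1.5, 0.3, 0.2, 0, 1), 3, 3)
  shifted <- sweep(h1 %*% amat, 2, c(5, -2, 0.1), "+")
  expect_equal(cca_layer(shifted, h2, 1e-12, 1e-12, 3)$correlation, base,
               tolerance = 1e-8)
})

test_that("cca_layer rejects rank-deficient sample sizes and bad input", {
  h <- matrix(rnorm(12), 4, 3)
  expect_error(cca_layer(h, h, 1e-4, 1e-4, dims = 4),
               class = "seizecca_error_numeric")
  h2 <- h
  h2[1, 1] <- NaN
  expect_error(cca_layer(h2, h, 1e-4, 1e-4, 2), class = "seizecca_error_numeric")
})

test_that("KL sparsity matches hand-computed values and Gibbs' inequality", {
  expect_equal(kl_sparsity(0.05, rep(0.05, 7)), 0)
  hand <- 0.05 * log(0.05 / 0.5) + 0.95 * log(0.95 / 0.5)
  expect_equal(kl_sparsity(0.05, 0.5), hand, tolerance = 1e-10)
  expect_equal(kl_sparsity(0.05, 0.5), 0.4946, tolerance = 1e-4)
  set.seed(35)
  for (i in 1:1000) {
    expect_gte(kl_sparsity(runif(1, 0.01, 0.99), runif(3)), 0)
  }
  # clamping keeps the penalty finite at the boundary
  expect_true(is.finite(kl_sparsity(0.05, c(0, 1))))
  expect_error(kl_sparsity(0, 0.5), class = "seizecca_error_config")
})

test_that("loss components decompose as the weighted sum", {
  tbl <- easy_binary_table(n_per_class = 30, n_features = 6, informative = 1:2,
                           seed = 36)
  cfg <- dcsae_config(hidden_sizes_f = 5, hidden_sizes_g = 3, epochs = 2,
                      dropout_rate = 0, batch_size = 64, seed = 1)
  fit <- train_dcsae(tbl, config = cfg)
  parts <- seizecca:::split_table(tbl, "y")

  comp <- dcsae_loss(fit, parts$x, labels = parts$y)
  expect_equal(comp$total,
               -comp$correlation + comp$reconstruction_x + comp$reconstruction_y +
                 comp$sparsity_f + comp$sparsity_g)

  # zeroing lambda and the sparsity weights leaves only the correlation term
  bare <- fit
  bare$config$recon_weight <- 0
  bare$config$sparsity_weight_f <- 0
  bare$config$sparsity_weight_g <- 0
  comp0 <- dcsae_loss(bare, parts$x, labels = parts$y)
  expect_equal(comp0$total, -comp0$correlation)
  expect_equal(comp0$correlation, comp$correlation)

  # doubling lambda doubles the reconstruction components only
  dbl <- fit
  dbl$config$recon_weight <- 2 * fit$config$recon_weight
  comp2 <- dcsae_loss(dbl, parts$x, labels = parts$y)
  expect_equal(comp2$reconstruction_x, 2 * comp$reconstruction_x)
  expect_equal(comp2$reconstruction_y, 2 * comp$reconstruction_y)
  expect_equal(comp2$sparsity_f, comp$sparsity_f)
  expect_equal(comp2$correlation, comp$correlation)
})

test_that("perfect autoencoders have zero reconstruction loss", {
  tbl <- easy_binary_table(n_per_class = 20, n_features = 3, informative = 1,
                           seed = 37)
  cfg <- dcsae_config(hidden_sizes_f = 3, hidden_sizes_g = 2, epochs = 1,
                      activation = "linear", dropout_rate = 0, momentum = 0,
                      sparsity_weight_f = 0, sparsity_weight_g = 0, seed = 1)
  fit <- train_dcsae(tbl, config = cfg)
  identity_layer <- function(d) list(list(w = diag(d), b = numeric(d)))
  fit$nets$encoder_f$layers <- identity_layer(3)
  fit$nets$decoder_f$layers <- identity_layer(3)
  fit$nets$encoder_g$layers <- identity_layer(2)
  fit$nets$decoder_g$layers <- identity_layer(2)
  parts <- seizecca:::split_table(tbl, "y")
  comp <- dcsae_loss(fit, parts$x, labels = parts$y)
  expect_equal(comp$reconstruction_x, 0)
  expect_equal(comp$reconstruction_y, 0)
})

test_that("analytic gradients match finite differences of the total loss", {
  tbl <- easy_binary_table(n_per_class = 25, n_features = 6, informative = 1:2,
                           seed = 38)
  parts <- seizecca:::split_table(tbl, "y")
  views <- seizecca:::build_views(parts$x, parts$y, "labels")
  cfg <- dcsae_config(hidden_sizes_f = c(5, 4), hidden_sizes_g = 3,
                      recon_weight = 0.7, sparsity_weight_f = 0.3,
                      sparsity_weight_g = 0.2, dropout_rate = 0, seed = 7)
  dims <- 2
  set.seed(39)
  nets <- list(
    encoder_f = seizecca:::net_init(6, c(5, 4), "sigmoid"),
    decoder_f = seizecca:::net_init(4, 5, "sigmoid", linear_out = TRUE, out_dim = 6),
    encoder_g = seizecca:::net_init(2, 3, "sigmoid"),
    decoder_g = seizecca:::net_init(3, integer(0), "sigmoid",
                                    linear_out = TRUE, out_dim = 2)
  )
  loss_of <- function(nets) {
    seizecca:::loss_components(nets, views$x, views$yv, cfg, dims)$total
  }
  analytic <- local({
    x <- views$x; yv <- views$yv; n <- nrow(x)
    a_f <- seizecca:::net_forward(nets$encoder_f, x)
    a_g <- seizecca:::net_forward(nets$encoder_g, yv)
    cca <- seizecca:::cca_core(a_f[[length(a_f)]], a_g[[length(a_g)]],
                               cfg$reg_x, cfg$reg_y, dims, grad = TRUE)
    a_df <- seizecca:::net_forward(nets$decoder_f, a_f[[length(a_f)]])
    bdf <- seizecca:::net_backward(nets$decoder_f, a_df,
                                   2 * cfg$recon_weight * (a_df[[length(a_df)]] - x) / n)
    exf <- seizecca:::sparsity_extra_grads(nets$encoder_f, a_f,
                                           cfg$sparsity_target_f, cfg$sparsity_weight_f)
    bef <- seizecca:::net_backward(nets$encoder_f, a_f, -cca$d_h1 + bdf$d_input,
                                   d_extra = exf)
    list(encoder_f = bef$grads, decoder_f = bdf$grads)
  })
  eps <- 1e-6
  set.seed(40)
  for (net in c("encoder_f", "decoder_f")) {
    for (layer in seq_along(nets[[net]]$layers)) {
      w <- nets[[net]]$layers[[layer]]$w
      i <- sample(nrow(w), 1)
      j <- sample(ncol(w), 1)
      plus <- nets; plus[[net]]$layers[[layer]]$w[i, j] <- w[i, j] + eps
      minus <- nets; minus[[net]]$layers[[layer]]$w[i, j] <- w[i, j] - eps
      numeric_grad <- (loss_of(plus) - loss_of(minus)) / (2 * eps)
      expect_equal(unname(analytic[[net]][[layer]]$w[i, j]), numeric_grad,
                   tolerance = 1e-5)
    }
  }
})

test_that("training is deterministic and logs every component", {
  tbl <- easy_binary_table(n_per_class = 25, n_features = 8, seed = 41)
  cfg <- dcsae_config(hidden_sizes_f = 6, hidden_sizes_g = 3, epochs = 4, seed = 5)
  f1 <- train_dcsae(tbl, config = cfg)
  f2 <- train_dcsae(tbl, config = cfg)
  expect_identical(f1$training_log, f2$training_log)
  expect_identical(f1$u, f2$u)
  expect_equal(nrow(f1$training_log), 4)
  expect_named(f1$training_log,
               c("epoch", "total", "correlation", "reconstruction_x",
                 "reconstruction_y", "sparsity_f", "sparsity_g"))
})

test_that("full-batch descent holds in the linear regime at a small step", {
  set.seed(42)
  n <- 200
  z <- matrix(rnorm(n * 2), n, 2)
  x <- z %*% matrix(rnorm(8), 2, 4) + 0.5 * matrix(rnorm(n * 4), n, 4)
  y <- z %*% matrix(rnorm(8), 2, 4) + 0.5 * matrix(rnorm(n * 4), n, 4)
  tbl <- tibble::as_tibble(as.data.frame(cbind(x, y)))
  names(tbl) <- paste0("X", 1:8)
  tbl$y <- rep(0:1, length.out = n)
  cfg <- dcsae_config(hidden_sizes_f = 4, hidden_sizes_g = 4, canonical_dims = 2,
                      recon_weight = 0, sparsity_weight_f = 0,
                      sparsity_weight_g = 0, activation = "linear",
                      learning_rate = 1e-3, momentum = 0, dropout_rate = 0,
                      batch_size = 1000, epochs = 12,
                      reg_x = 1e-8, reg_y = 1e-8, seed = 2)
  fit <- train_dcsae(tbl, view = "split", config = cfg)
  expect_true(all(diff(fit$training_log$total) <= 1e-9))
})

test_that("a stronger sparsity penalty pulls activations toward the target", {
  tbl <- easy_binary_table(n_per_class = 60, n_features = 12, informative = 1:3,
                           seed = 43)
  norm <- apply_minmax(tbl, fit_minmax(tbl))
  parts <- seizecca:::split_table(norm, "y")
  gap <- vapply(c(0, 0.1, 1), function(w) {
    fit <- train_dcsae(norm, config = dcsae_config(
      hidden_sizes_f = c(10, 6), epochs = 20, sparsity_weight_f = w,
      sparsity_weight_g = w, dropout_rate = 0, seed = 9))
    a <- seizecca:::net_forward(fit$nets$encoder_f, parts$x)
    acts <- unlist(lapply(seq_along(fit$nets$encoder_f$layers),
                          function(l) colMeans(a[[l + 1]])))
    mean(abs(acts - 0.05))
  }, numeric(1))
  expect_gt(gap[1], gap[2])
  expect_gt(gap[2], gap[3])
})

test_that("prediction assigns nearest centroids with ties to the lower class", {
  model <- structure(list(
    nets = list(encoder_f = list(layers = list(list(w = matrix(1), b = 0)),
                                 activation = "linear", linear_out = FALSE)),
    u = matrix(1), h1_mean = 0,
    centroids = rbind(`0` = -1, `1` = 1),
    classes = c(0L, 1L), features = "X1",
    config = dcsae_config(), dims = 1L, view = "labels"
  ), class = "dcsae")
  pred <- predict(model, tibble::tibble(X1 = c(-1, 1, 0, 0.2)))
  expect_identical(pred$.pred_class, c(0L, 1L, 0L, 1L))  # 0 wins the tie at 0
  expect_equal(pred$.score_0, -abs(c(-1, 1, 0, 0.2) - (-1)))

  # a training point on its centroid is assigned that class
  expect_identical(pred$.pred_class[1], 0L)
  expect_error(predict(model, tibble::tibble(Z = 1)), class = "seizecca_error_shape")
})

test_that("the model serializes to JSON and predicts identically after reload", {
  tbl <- easy_binary_table(n_per_class = 25, n_features = 6, seed = 44)
  fit <- train_dcsae(tbl, config = dcsae_config(hidden_sizes_f = 5,
                                                hidden_sizes_g = 3,
                                                epochs = 3, seed = 3))
  path <- withr::local_tempfile(fileext = ".json")
  save_dcsae(fit, path)
  back <- load_dcsae(path)
  expect_equal(predict(back, tbl), predict(fit, tbl), tolerance = 1e-12)
})

test_that("training reports divergence with the failing epoch", {
  tbl <- easy_binary_table(n_per_class = 20, n_features = 5, seed = 45)
  cfg <- dcsae_config(hidden_sizes_f = 4, hidden_sizes_g = 3, epochs = 5,
                      learning_rate = 1e6, momentum = 0,
                      activation = "linear", seed = 1)
  err <- tryCatch(train_dcsae(tbl, config = cfg), error = identity)
  expect_s3_class(err, "seizecca_error_numeric")
  expect_match(conditionMessage(err), "epoch")
})
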