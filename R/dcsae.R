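#' Configuration for the deep canonically correlated sparse autoencoder
#'
#' The classifier couples two encoder/decoder networks `f` (feature view)
#' and `g` (second view) through a regularized canonical-correlation
#' objective on their top-layer outputs, plus sparse-autoencoder
#' reconstruction and KL sparsity penalties. The combined training loss is
#'
#' `-(1/N) tr(U' f(X) g(Y)' V) + (lambda/N) sum_i(||xhat_i - x_i||^2 +
#'  ||yhat_i - y_i||^2) + alpha_s KL(rho || rho_hat) + beta_s KL(sigma ||
#'  sigma_hat)`
#'
#' where `U`, `V` are canonical direction matrices satisfying the whitening
#' constraints `U'((1/N) H1c' H1c + r_x I) U = I` (and the `V` analogue).
#'
#' Sparse hidden layers use the logistic activation so mean activations live
#' in `(0, 1)` and the Bernoulli KL penalty is well defined; decoders end in
#' a linear output layer. `activation = "linear"` replaces every encoder
#' nonlinearity by the identity, which reduces the correlation term to
#' classical CCA.
#'
#' @param hidden_sizes_f,hidden_sizes_g Integer vectors of encoder layer
#'   widths for the feature view and the second view.
#' @param canonical_dims Number of canonical directions `L`; `NULL` resolves
#'   at training time to `min(10, 2 * n_classes, last f width, last g width)`.
#' @param reg_x,reg_y Ridge terms added to the view auto-covariances.
#' @param recon_weight Reconstruction weight `lambda`.
#' @param sparsity_weight_f,sparsity_weight_g KL penalty weights.
#' @param sparsity_target_f,sparsity_target_g Target mean activations
#'   (`rho`, `sigma`) in `(0, 1)`.
#' @param learning_rate Gradient-descent step size (default 0.01).
#' @param momentum Classical momentum on all gradient steps (default 0.9;
#'   0 gives plain gradient descent).
#' @param epochs Training epochs (default 50).
#' @param batch_size Minibatch size for the reconstruction/sparsity stream;
#'   the correlation term is always evaluated full-batch.
#' @param dropout_rate Dropout probability on encoder hidden activations in
#'   the reconstruction stream (default 0.5).
#' @param activation `"sigmoid"` (default) or `"linear"`.
#' @param seed Integer seed controlling initialisation, shuffling, dropout.
#' @return A list of class `dcsae_config`.
#' @export
dcsae_config <- function(hidden_sizes_f = c(32, 16),
                         hidden_sizes_g = 8,
                         canonical_dims = NULL,
                         reg_x = 1e-4,
                         reg_y = 1e-4,
                         recon_weight = 1,
                         sparsity_weight_f = 0.1,
                         sparsity_weight_g = 0.1,
                         sparsity_target_f = 0.05,
                         sparsity_target_g = 0.05,
                         learning_rate = 0.01,
                         momentum = 0.9,
                         epochs = 50,
                         batch_size = 64,
                         dropout_rate = 0.5,
                         activation = c("sigmoid", "linear"),
                         seed = 1) {
  activation <- rlang::arg_match(activation)
  if (any(hidden_sizes_f < 1) || any(hidden_sizes_g < 1)) {
    stop_config("Hidden sizes must be positive integers.")
  }
  if (reg_x <= 0 || reg_y <= 0) stop_config("`reg_x` and `reg_y` must be positive.")
  if (recon_weight < 0 || sparsity_weight_f < 0 || sparsity_weight_g < 0) {
    stop_config("Loss weights must be non-negative.")
  }
  for (t in c(sparsity_target_f, sparsity_target_g)) {
    if (t <= 0 || t >= 1) stop_config("Sparsity targets must lie in (0, 1).")
  }
  if (learning_rate <= 0) stop_config("`learning_rate` must be positive.")
  if (momentum < 0 || momentum >= 1) stop_config("`momentum` must be in [0, 1).")
  if (epochs < 1 || batch_size < 1) stop_config("`epochs` and `batch_size` must be positive.")
  if (dropout_rate < 0 || dropout_rate >= 1) stop_config("`dropout_rate` must be in [0, 1).")
  structure(
    list(
      hidden_sizes_f = as.integer(hidden_sizes_f),
      hidden_sizes_g = as.integer(hidden_sizes_g),
      canonical_dims = canonical_dims,
      reg_x = reg_x, reg_y = reg_y,
      recon_weight = recon_weight,
      sparsity_weight_f = sparsity_weight_f,
      sparsity_weight_g = sparsity_weight_g,
      sparsity_target_f = sparsity_target_f,
      sparsity_target_g = sparsity_target_g,
      learning_rate = learning_rate,
      momentum = momentum,
      epochs = as.integer(epochs),
      batch_size = as.integer(batch_size),
      dropout_rate = dropout_rate,
      activation = activation,
      seed = as.integer(seed)
    ),
    class = "dcsae_config"
  )
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Xavier-uniform network initialisation. `sizes` are the layer widths after
# the input; decoders get a final linear layer back to `out_dim`.
net_init <- function(in_dim, sizes, activation, linear_out = FALSE, out_dim = NULL) {
  dims <- c(in_dim, sizes, if (linear_out) out_dim)
  layers <- vector("list", length(dims) - 1L)
  for (l in seq_along(layers)) {
    limit <- sqrt(6 / (dims[l] + dims[l + 1]))
    layers[[l]] <- list(
      w = matrix(runif(dims[l] * dims[l + 1], -limit, limit), nrow = dims[l]),
      b = numeric(dims[l + 1])
    )
  }
  list(layers = layers, activation = activation, linear_out = linear_out)
}

# Forward pass keeping all activations; `masks` are optional dropout masks
# (already inverted-scaled) applied after each nonlinear layer.
net_forward <- function(net, x, masks = NULL) {
  n_layers <- length(net$layers)
  a <- vector("list", n_layers + 1L)
  a[[1]] <- x
  for (l in seq_len(n_layers)) {
    z <- sweep(a[[l]] %*% net$layers[[l]]$w, 2, net$layers[[l]]$b, "+")
    linear <- net$activation == "linear" || (net$linear_out && l == n_layers)
    h <- if (linear) z else sigmoid(z)
    if (!is.null(masks) && !is.null(masks[[l]])) h <- h * masks[[l]]
    a[[l + 1]] <- h
  }
  a
}

# Backward pass. `d_top` is the gradient at the network output; `d_extra`
# optionally adds per-layer gradients at the activations (sparsity terms).
# Returns per-layer weight/bias gradients and the gradient at the input.
net_backward <- function(net, a, d_top, d_extra = NULL, masks = NULL) {
  n_layers <- length(net$layers)
  grads <- vector("list", n_layers)
  d_a <- d_top
  for (l in rev(seq_len(n_layers))) {
    if (!is.null(d_extra) && !is.null(d_extra[[l]])) d_a <- d_a + d_extra[[l]]
    if (!is.null(masks) && !is.null(masks[[l]])) d_a <- d_a * masks[[l]]
    linear <- net$activation == "linear" || (net$linear_out && l == n_layers)
    h <- a[[l + 1]]
    if (!is.null(masks) && !is.null(masks[[l]])) {
      # activation before the dropout mask; recover it for the derivative
      safe <- masks[[l]]
      safe[safe == 0] <- 1
      h <- h / safe
    }
    d_z <- if (linear) d_a else d_a * h * (1 - h)
    grads[[l]] <- list(w = crossprod(a[[l]], d_z), b = colSums(d_z))
    d_a <- tcrossprod(d_z, net$layers[[l]]$w)
  }
  list(grads = grads, d_input = d_a)
}

# Gradient step with classical momentum; the velocity lives on the net so it
# persists across minibatches. momentum = 0 is plain gradient descent.
net_update <- function(net, grads, lr, momentum = 0) {
  if (is.null(net$vel)) {
    net$vel <- lapply(net$layers, function(l) list(w = l$w * 0, b = l$b * 0))
  }
  for (l in seq_along(net$layers)) {
    net$vel[[l]]$w <- momentum * net$vel[[l]]$w + grads[[l]]$w
    net$vel[[l]]$b <- momentum * net$vel[[l]]$b + grads[[l]]$b
    net$layers[[l]]$w <- net$layers[[l]]$w - lr * net$vel[[l]]$w
    net$layers[[l]]$b <- net$layers[[l]]$b - lr * net$vel[[l]]$b
  }
  net
}

# Symmetric inverse square root with eigenvalue clamping.
inv_sqrtm <- function(s, eps = 1e-12) {
  e <- eigen(s, symmetric = TRUE)
  vals <- pmax(e$values, eps)
  e$vectors %*% (t(e$vectors) / sqrt(vals))
}

# Core regularized-CCA solve on two activation matrices (rows = samples).
# Returns correlation (sum of top-L singular values), whitened direction
# matrices and, when `grad = TRUE`, the gradients of the correlation with
# respect to H1 and H2.
cca_core <- function(h1, h2, r_x, r_y, dims, grad = FALSE) {
  n <- nrow(h1)
  if (nrow(h2) != n) stop_shape("Both views must have the same number of rows.")
  dims <- as.integer(dims)
  if (n <= dims) {
    stop_numeric(sprintf("CCA needs more samples (%d) than canonical dimensions (%d).",
                         n, dims))
  }
  if (any(!is.finite(h1)) || any(!is.finite(h2))) {
    stop_numeric("Non-finite values entered the CCA layer.")
  }
  m1 <- colMeans(h1)
  m2 <- colMeans(h2)
  h1c <- sweep(h1, 2, m1)
  h2c <- sweep(h2, 2, m2)
  s11 <- crossprod(h1c) / n + diag(r_x, ncol(h1))
  s22 <- crossprod(h2c) / n + diag(r_y, ncol(h2))
  s12 <- crossprod(h1c, h2c) / n
  if (any(!is.finite(s11)) || any(!is.finite(s22))) {
    stop_numeric("Non-finite covariance in the CCA layer.")
  }
  s11_ih <- inv_sqrtm(s11)
  s22_ih <- inv_sqrtm(s22)
  tmat <- s11_ih %*% s12 %*% s22_ih
  sv <- svd(tmat)
  L <- min(dims, length(sv$d))
  p <- sv$u[, seq_len(L), drop = FALSE]
  q <- sv$v[, seq_len(L), drop = FALSE]
  d_l <- sv$d[seq_len(L)]
  u <- s11_ih %*% p
  v <- s22_ih %*% q
  out <- list(correlation = sum(d_l), u = u, v = v,
              singular_values = d_l, mean_x = m1, mean_y = m2)
  if (grad) {
    g12 <- u %*% t(v)
    g11 <- -0.5 * u %*% (d_l * t(u))
    g22 <- -0.5 * v %*% (d_l * t(v))
    out$d_h1 <- (2 * h1c %*% g11 + h2c %*% t(g12)) / n
    out$d_h2 <- (2 * h2c %*% g22 + h1c %*% g12) / n
  }
  out
}

#' Regularized CCA layer on two view matrices
#'
#' Centers both matrices, forms auto-covariances with ridge terms `r_x`,
#' `r_y` on the diagonal (normalising by `N`), and returns the sum of the
#' top-`dims` singular values of `S11^{-1/2} S12 S22^{-1/2}` together with
#' the whitened canonical direction matrices `U`, `V` (one column per
#' canonical pair) satisfying `U' S11 U = I`, `V' S22 V = I`. The returned
#' correlation lies in `[0, dims]`.
#'
#' @param h1,h2 `N x o1` and `N x o2` numeric matrices (rows = samples).
#' @param r_x,r_y Non-negative ridge regularizers.
#' @param dims Number of canonical directions `L` (`N` must exceed `L`).
#' @return List with `correlation`, `u`, `v`, `singular_values`, `mean_x`,
#'   `mean_y`.
#' @export
#' @examples
#' set.seed(1)
#' h <- matrix(rnorm(60), 20, 3)
#' cca_layer(h, h, r_x = 1e-12, r_y = 1e-12, dims = 3)$correlation  # ~3
cca_layer <- function(h1, h2, r_x = 1e-4, r_y = 1e-4, dims = min(ncol(h1), ncol(h2))) {
  cca_core(as.matrix(h1), as.matrix(h2), r_x, r_y, dims, grad = FALSE)
}

#' Bernoulli KL sparsity penalty
#'
#' `sum_j rho log(rho / rho_hat_j) + (1 - rho) log((1 - rho) / (1 -
#' rho_hat_j))`: the KL divergence between a Bernoulli with mean `rho`
#' (the sparsity target) and Bernoullis with the observed mean activations.
#' Mean activations are clamped to `[1e-6, 1 - 1e-6]` so the penalty is
#' total; it is non-negative and zero iff every `rho_hat_j == rho`.
#'
#' @param target Sparsity target in `(0, 1)`.
#' @param mean_activations Vector of observed mean activations.
#' @return Scalar penalty.
#' @export
#' @examples
#' kl_sparsity(0.05, c(0.05, 0.05))  # 0
#' kl_sparsity(0.05, 0.5)            # ~0.4946
kl_sparsity <- function(target, mean_activations) {
  if (!is_scalar_number(target) || target <= 0 || target >= 1) {
    stop_config("`target` must lie in (0, 1).")
  }
  r <- clamp(mean_activations, 1e-6, 1 - 1e-6)
  sum(target * log(target / r) + (1 - target) * log((1 - target) / (1 - r)))
}

# Derivative of the KL penalty with respect to each mean activation.
kl_sparsity_grad <- function(target, mean_activations) {
  r <- clamp(mean_activations, 1e-6, 1 - 1e-6)
  inside <- mean_activations > 1e-6 & mean_activations < 1 - 1e-6
  ((1 - target) / (1 - r) - target / r) * inside
}

# Mean activations of every nonlinear encoder layer (list, one vector per
# layer; NULL for linear layers where the penalty does not apply).
encoder_mean_activations <- function(net, a) {
  lapply(seq_along(net$layers), function(l) {
    if (net$activation == "linear") NULL else colMeans(a[[l + 1]])
  })
}

sparsity_penalty <- function(net, a, target) {
  ms <- encoder_mean_activations(net, a)
  sum(vapply(ms, function(m) if (is.null(m)) 0 else kl_sparsity(target, m), numeric(1)))
}

# Per-layer activation gradients of the sparsity penalty (for net_backward).
sparsity_extra_grads <- function(net, a, target, weight) {
  lapply(seq_along(net$layers), function(l) {
    if (net$activation == "linear" || weight == 0) return(NULL)
    m <- colMeans(a[[l + 1]])
    g <- weight * kl_sparsity_grad(target, m) / nrow(a[[l + 1]])
    matrix(g, nrow = nrow(a[[l + 1]]), ncol = length(g), byrow = TRUE)
  })
}

resolve_dims <- function(config, n_classes) {
  config$canonical_dims %||%
    min(10L, 2L * n_classes,
        tail(config$hidden_sizes_f, 1), tail(config$hidden_sizes_g, 1))
}

# Build the two training views from a feature table.
build_views <- function(x, labels, view) {
  if (view == "labels") {
    classes <- sort(unique(labels))
    yv <- outer(labels, classes, "==") * 1
    colnames(yv) <- paste0("class", classes)
    list(x = x, yv = yv)
  } else {
    d <- ncol(x)
    if (d < 2) stop_shape("Split view needs at least two feature columns.")
    half <- floor(d / 2)
    list(x = x[, seq_len(half), drop = FALSE],
         yv = x[, (half + 1):d, drop = FALSE])
  }
}

#' Evaluate the combined DCSAE loss and its components
#'
#' Computes the full-batch loss
#' `-correlation + reconstruction_x + reconstruction_y + sparsity_f +
#' sparsity_g` at the model's current parameters, where the reconstruction
#' components carry the `lambda / N` scaling and the sparsity components the
#' `alpha_s` / `beta_s` weights.
#'
#' @param model A fitted or in-training [train_dcsae()] model.
#' @param x Feature-view matrix (`N x d_x`).
#' @param y_view Second-view matrix (`N x d_y`); `NULL` rebuilds the label
#'   view from `labels`.
#' @param labels Optional integer labels used when `y_view` is `NULL`.
#' @return List with `total`, `correlation`, `reconstruction_x`,
#'   `reconstruction_y`, `sparsity_f`, `sparsity_g`.
#' @export
dcsae_loss <- function(model, x, y_view = NULL, labels = NULL) {
  config <- model$config
  x <- as.matrix(x)
  if (is.null(y_view)) {
    if (is.null(labels)) stop_shape("Provide `y_view` or `labels`.")
    y_view <- build_views(x, as.integer(labels), "labels")$yv
  }
  y_view <- as.matrix(y_view)
  loss_components(model$nets, x, y_view, config, model$dims)
}

loss_components <- function(nets, x, yv, config, dims) {
  n <- nrow(x)
  a_f <- net_forward(nets$encoder_f, x)
  a_g <- net_forward(nets$encoder_g, yv)
  h1 <- a_f[[length(a_f)]]
  h2 <- a_g[[length(a_g)]]
  cca <- cca_core(h1, h2, config$reg_x, config$reg_y, dims, grad = FALSE)
  xhat <- net_forward(nets$decoder_f, h1)
  yhat <- net_forward(nets$decoder_g, h2)
  xhat <- xhat[[length(xhat)]]
  yhat <- yhat[[length(yhat)]]
  recon_x <- config$recon_weight * sum((xhat - x)^2) / n
  recon_y <- config$recon_weight * sum((yhat - yv)^2) / n
  sp_f <- config$sparsity_weight_f *
    sparsity_penalty(nets$encoder_f, a_f, config$sparsity_target_f)
  sp_g <- config$sparsity_weight_g *
    sparsity_penalty(nets$encoder_g, a_g, config$sparsity_target_g)
  list(
    total = -cca$correlation + recon_x + recon_y + sp_f + sp_g,
    correlation = cca$correlation,
    reconstruction_x = recon_x,
    reconstruction_y = recon_y,
    sparsity_f = sp_f,
    sparsity_g = sp_g
  )
}

# One autoencoder-stream gradient step (reconstruction + sparsity) for a
# single view, on the given row subset. Returns updated nets.
ae_step <- function(enc, dec, x, lambda, sp_weight, sp_target, lr, dropout,
                    n_scale, momentum = 0) {
  masks <- NULL
  if (dropout > 0 && enc$activation != "linear") {
    masks <- lapply(seq_along(enc$layers), function(l) {
      width <- ncol(enc$layers[[l]]$w)
      keep <- matrix(runif(nrow(x) * width) >= dropout, nrow(x), width)
      keep / (1 - dropout)
    })
  }
  a_e <- net_forward(enc, x, masks)
  h <- a_e[[length(a_e)]]
  a_d <- net_forward(dec, h)
  xhat <- a_d[[length(a_d)]]
  d_xhat <- 2 * lambda * (xhat - x) / n_scale
  back_d <- net_backward(dec, a_d, d_xhat)
  extra <- sparsity_extra_grads(enc, a_e, sp_target, sp_weight)
  back_e <- net_backward(enc, a_e, back_d$d_input, d_extra = extra, masks = masks)
  list(enc = net_update(enc, back_e$grads, lr, momentum),
       dec = net_update(dec, back_d$grads, lr, momentum))
}

#' Train the deep canonically correlated sparse autoencoder classifier
#'
#' Trains two encoder/decoder networks by plain gradient descent on the
#' combined DCSAE loss. Per epoch, the reconstruction and sparsity terms are
#' stepped on seeded minibatches of `batch_size` rows (with dropout on the
#' encoder hidden activations), then the correlation term takes one
#' full-batch step — minibatch covariance estimates of the CCA objective are
#' rank-deficient, so the canonical term is always computed on all rows.
#' After the final epoch the canonical directions `U`, `V` are recomputed
#' from the clean encoder outputs on the whole training set and per-class
#' centroids of the canonical projections `U'(f(x) - mean)` are stored for
#' nearest-centroid prediction.
#'
#' @param data Feature table (tibble) with a label column.
#' @param label_column Name of the label column.
#' @param view Second view for the canonical correlation: `"labels"`
#'   (one-hot class indicators; supervised, the default) or `"split"` (the
#'   feature vector halved into two views).
#' @param config A [dcsae_config()].
#' @return An object of class `dcsae` with elements `nets`, `u`, `v`,
#'   `h1_mean`, `centroids`, `classes`, `features`, `training_log` (tibble
#'   of per-epoch loss components), `dims`, `config`, `view`.
#' @seealso [predict.dcsae()], [dcsae_loss()], [tidy.dcsae()]
#' @export
#' @examples
#' tbl <- simulate_eeg_segments(n_per_class = 40, n_classes = 2,
#'                              n_features = 10, informative = 1:3,
#'                              class_separation = 2, seed = 1)
#' fit <- train_dcsae(tbl, config = dcsae_config(hidden_sizes_f = 8,
#'                                               epochs = 5, seed = 1))
#' predict(fit, tbl[1:3, ])
train_dcsae <- function(data, label_column = "y",
                        view = c("labels", "split"),
                        config = dcsae_config()) {
  view <- rlang::arg_match(view)
  parts <- split_table(data, label_column)
  labels <- parts$y
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop_label("Training needs at least two classes.")
  views <- build_views(parts$x, labels, view)
  x <- views$x
  yv <- views$yv
  n <- nrow(x)
  dims <- min(resolve_dims(config, length(classes)), ncol(x), ncol(yv))
  if (n <= dims) stop_numeric("Need more rows than canonical dimensions.")

  set.seed(derive_seed(config$seed, 3L))
  nets <- list(
    encoder_f = net_init(ncol(x), config$hidden_sizes_f, config$activation),
    decoder_f = net_init(tail(config$hidden_sizes_f, 1),
                         rev(head(config$hidden_sizes_f, -1)),
                         config$activation, linear_out = TRUE, out_dim = ncol(x)),
    encoder_g = net_init(ncol(yv), config$hidden_sizes_g, config$activation),
    decoder_g = net_init(tail(config$hidden_sizes_g, 1),
                         rev(head(config$hidden_sizes_g, -1)),
                         config$activation, linear_out = TRUE, out_dim = ncol(yv))
  )

  log <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    set.seed(derive_seed(config$seed, 100L + epoch))
    order <- sample.int(n)
    starts <- seq(1, n, by = config$batch_size)
    for (s in starts) {
      rows <- order[s:min(s + config$batch_size - 1L, n)]
      if (length(rows) < 2) next
      stepped <- ae_step(nets$encoder_f, nets$decoder_f, x[rows, , drop = FALSE],
                         config$recon_weight, config$sparsity_weight_f,
                         config$sparsity_target_f, config$learning_rate,
                         config$dropout_rate, length(rows), config$momentum)
      nets$encoder_f <- stepped$enc
      nets$decoder_f <- stepped$dec
      stepped <- ae_step(nets$encoder_g, nets$decoder_g, yv[rows, , drop = FALSE],
                         config$recon_weight, config$sparsity_weight_g,
                         config$sparsity_target_g, config$learning_rate,
                         config$dropout_rate, length(rows), config$momentum)
      nets$encoder_g <- stepped$enc
      nets$decoder_g <- stepped$dec
      # Canonical-correlation ascent step: the covariances are always
      # estimated on the full training set (minibatch estimates are
      # rank-deficient), one step after every reconstruction minibatch.
      a_f <- net_forward(nets$encoder_f, x)
      a_g <- net_forward(nets$encoder_g, yv)
      cca <- cca_core(a_f[[length(a_f)]], a_g[[length(a_g)]],
                      config$reg_x, config$reg_y, dims, grad = TRUE)
      back_f <- net_backward(nets$encoder_f, a_f, -cca$d_h1)
      back_g <- net_backward(nets$encoder_g, a_g, -cca$d_h2)
      nets$encoder_f <- net_update(nets$encoder_f, back_f$grads,
                                   config$learning_rate, config$momentum)
      nets$encoder_g <- net_update(nets$encoder_g, back_g$grads,
                                   config$learning_rate, config$momentum)
    }

    comp <- loss_components(nets, x, yv, config, dims)
    if (!is.finite(comp$total)) {
      stop_numeric(sprintf("Training diverged (non-finite loss) at epoch %d.", epoch))
    }
    log[[epoch]] <- tibble::tibble(
      epoch = epoch, total = comp$total, correlation = comp$correlation,
      reconstruction_x = comp$reconstruction_x,
      reconstruction_y = comp$reconstruction_y,
      sparsity_f = comp$sparsity_f, sparsity_g = comp$sparsity_g
    )
  }

  a_f <- net_forward(nets$encoder_f, x)
  a_g <- net_forward(nets$encoder_g, yv)
  h1 <- a_f[[length(a_f)]]
  cca <- cca_core(h1, a_g[[length(a_g)]], config$reg_x, config$reg_y, dims,
                  grad = FALSE)
  z <- sweep(h1, 2, cca$mean_x) %*% cca$u
  centroids <- do.call(rbind, lapply(classes, function(cl) {
    colMeans(z[labels == cl, , drop = FALSE])
  }))
  rownames(centroids) <- classes

  structure(
    list(
      nets = nets, u = cca$u, v = cca$v,
      singular_values = cca$singular_values,
      h1_mean = cca$mean_x, h2_mean = cca$mean_y,
      centroids = centroids, classes = classes,
      features = if (view == "labels") parts$features else
        parts$features[seq_len(ncol(x))],
      training_log = dplyr::bind_rows(log),
      dims = dims, config = config, view = view,
      label_column = label_column, n_train = n
    ),
    class = "dcsae"
  )
}

#' Predict classes from canonical projections
#'
#' Projects each row as `U'(f(x) - mean)` and assigns the class of the
#' nearest centroid (Euclidean distance); ties break toward the lower class
#' index. Per-class scores are the negated distances, usable for ROC
#' analysis.
#'
#' @param object A fitted `dcsae` model.
#' @param new_data Feature table (tibble); a label column, if present, is
#'   ignored.
#' @param ... Unused.
#' @return A tibble with `.pred_class` (integer) and one `.score_<class>`
#'   column per class.
#' @export
predict.dcsae <- function(object, new_data, ...) {
  if (is.null(object$centroids)) abort("Model has no trained centroids.",
                                       class = "seizecca_error_state")
  feats <- object$features
  missing <- setdiff(feats, names(new_data))
  if (length(missing) > 0) {
    stop_shape(sprintf("new_data lacks feature column(s): %s",
                       paste(head(missing, 5), collapse = ", ")))
  }
  x <- as.matrix(new_data[, feats, drop = FALSE])
  a <- net_forward(object$nets$encoder_f, x)
  z <- sweep(a[[length(a)]], 2, object$h1_mean) %*% object$u
  k <- nrow(object$centroids)
  dist2 <- vapply(seq_len(k), function(i) {
    rowSums(sweep(z, 2, object$centroids[i, ])^2)
  }, numeric(nrow(z)))
  dist2 <- matrix(dist2, nrow = nrow(z))
  pred <- object$classes[max.col(-dist2, ties.method = "first")]
  scores <- -sqrt(dist2)
  colnames(scores) <- paste0(".score_", object$classes)
  out <- tibble::as_tibble(as.data.frame(scores))
  out <- dplyr::bind_cols(tibble::tibble(.pred_class = as.integer(pred)), out)
  out
}

#' @export
print.dcsae <- function(x, ...) {
  cat(sprintf(
    "Deep canonically correlated sparse autoencoder\n%d features -> %d canonical dims, %d classes, view = '%s'\n",
    length(x$features), x$dims, length(x$classes), x$view
  ))
  cat(sprintf("Final correlation %.4f (max %d) after %d epochs\n",
              tail(x$training_log$correlation, 1), x$dims, x$config$epochs))
  invisible(x)
}
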