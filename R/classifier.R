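# Fast linear classifier used as the default wrapper error estimator:
# regularised linear discriminant analysis (ridge on the pooled within-class
# covariance, class priors from the training frequencies). Closed form,
# deterministic, cheap enough for thousands of fitness evaluations inside
# the feature-selection loop, and — unlike least squares on one-hot
# indicators — immune to class masking when class means are collinear.

lda_ridge_fit <- function(x, y, lambda = 1e-3) {
  classes <- sort(unique(y))
  d <- ncol(x)
  means <- matrix(vapply(classes, function(cl) colMeans(x[y == cl, , drop = FALSE]),
                         numeric(d)),
                  nrow = length(classes), ncol = d, byrow = TRUE)
  xc <- x - means[match(y, classes), , drop = FALSE]
  sw <- crossprod(xc) / nrow(x) + diag(lambda, d)
  list(
    classes = classes,
    means = means,
    sw_inv = chol2inv(chol(sw)),
    log_priors = log(as.numeric(table(factor(y, levels = classes))) / length(y))
  )
}

lda_ridge_predict <- function(fit, x) {
  scores <- vapply(seq_along(fit$classes), function(i) {
    centred <- sweep(x, 2, fit$means[i, ])
    -0.5 * rowSums((centred %*% fit$sw_inv) * centred) + fit$log_priors[i]
  }, numeric(nrow(x)))
  scores <- matrix(scores, nrow = nrow(x))
  fit$classes[max.col(scores, ties.method = "first")]
}

# Stratified k-fold CV misclassification rate in [0, 1].
linear_cv_error <- function(x, y, k = 3, lambda = 1e-3, seed = 0) {
  folds <- stratified_folds(y, k, seed)
  wrong <- 0L
  for (f in seq_len(k)) {
    test <- folds == f
    if (!any(test) || length(unique(y[!test])) < 2) next
    fit <- lda_ridge_fit(x[!test, , drop = FALSE], y[!test], lambda)
    pred <- lda_ridge_predict(fit, x[test, , drop = FALSE])
    wrong <- wrong + sum(pred != y[test])
  }
  wrong / length(y)
}
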