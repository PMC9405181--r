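# Shared fixtures: small synthetic tables and an independent CCA oracle.

easy_binary_table <- function(n_per_class = 50, n_features = 12,
                              informative = 1:3, separation = 2, seed = 1) {
  simulate_eeg_segments(
    n_per_class = n_per_class, n_classes = 2, n_features = n_features,
    informative = informative, class_separation = separation, seed = seed
  )
}

# Brute-force classical CCA through the generalized eigenproblem
# solve(S11) S12 solve(S22) S21: eigenvalues are squared canonical
# correlations. Independent of the package's whitened-SVD route.
oracle_cca_correlations <- function(h1, h2, ridge = 0) {
  n <- nrow(h1)
  h1c <- scale(h1, scale = FALSE)
  h2c <- scale(h2, scale = FALSE)
  s11 <- crossprod(h1c) / n + diag(ridge, ncol(h1))
  s22 <- crossprod(h2c) / n + diag(ridge, ncol(h2))
  s12 <- crossprod(h1c, h2c) / n
  m <- solve(s11, s12) %*% solve(s22, t(s12))
  ev <- eigen(m, only.values = TRUE)$values
  sqrt(pmax(0, Re(ev)))
}

# Mann-Whitney AUC oracle: fraction of (positive, negative) score pairs won,
# ties counted half.
oracle_mw_auc <- function(scores, positive) {
  sp <- scores[positive]
  sn <- scores[!positive]
  wins <- outer(sp, sn, ">") + 0.5 * outer(sp, sn, "==")
  mean(wins)
}
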