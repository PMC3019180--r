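# shared fixtures built in code

# small labeled universe + features, cheap enough for unit tests
quick_sim <- function(seed = 1, n_pos = 12, n_neg = 16, n_unlabeled = 0,
                      effect_size = 3, noise_sd = 0.3, ...) {
  simulate_study(simulation_config(n_pos = n_pos, n_neg = n_neg,
                                   n_unlabeled = n_unlabeled,
                                   effect_size = effect_size,
                                   noise_sd = noise_sd, seed = seed, ...))
}

sim_labels <- function(sim) {
  keep <- sim$genes$label != "unlabeled"
  ifelse(sim$genes$label[keep] == "positive", 1, -1)
}

sim_training_fm <- function(sim, mode = "combined_contin", ...) {
  fm <- build_feature_matrix(sim$genes, sim$expression, sim$peaks, mode, ...)
  ids <- sim$genes$gene_id[sim$genes$label != "unlabeled"]
  stemsvm:::fm_row_subset(fm, ids)
}

# two well-separated Gaussian clouds
make_separable <- function(n_per_class = 10, d = 2, gap = 6, seed = 1,
                           sd = 0.3) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_class * d, gap / 2, sd), n_per_class),
             matrix(rnorm(n_per_class * d, -gap / 2, sd), n_per_class))
  rownames(X) <- sprintf("g%02d", seq_len(2 * n_per_class))
  list(X = X, y = rep(c(1, -1), each = n_per_class))
}

# dual objective value of a trained model, for solver comparisons
dual_objective <- function(K, y, alpha) {
  Q <- (y %o% y) * K
  sum(alpha) - 0.5 * as.numeric(t(alpha) %*% Q %*% alpha)
}

# reference dual solution via quadprog (independent of the SMO path)
quadprog_svm <- function(K, y, C, ridge = 1e-9) {
  n <- length(y)
  D <- (y %o% y) * K + diag(ridge * (1 + sum(diag(K)) / n), n)
  sol <- quadprog::solve.QP(D, rep(1, n),
                            cbind(y, diag(n), -diag(n)),
                            c(0, rep(0, n), rep(-C, n)), meq = 1)
  alpha <- pmin(pmax(sol$solution, 0), C)
  free <- alpha > 1e-6 & alpha < C - 1e-6
  f0 <- as.numeric(K %*% (alpha * y))
  b <- if (any(free)) mean(y[free] - f0[free]) else 0
  list(alpha = alpha, b = b)
}

# brute-force quantile normalization: sort, average, map back by rank
brute_qn <- function(M) {
  S <- apply(M, 2, sort)
  ref <- rowMeans(S)
  out <- M
  for (j in seq_len(ncol(M))) {
    r <- rank(M[, j], ties.method = "average")
    out[, j] <- (ref[floor(r)] + ref[ceiling(r)]) / 2
  }
  out
}

# exhaustive hypergeometric upper tail
brute_hyper_p <- function(overlap, nA, nB, universe) {
  ks <- overlap:min(nA, nB)
  sum(choose(nA, ks) * choose(universe - nA, nB - ks)) / choose(universe, nB)
}
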