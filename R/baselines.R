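#' Comparison classifiers: LDA, decision tree, small neural net
#'
#' Reference methods the SVM is benchmarked against, each evaluated by
#' leave-one-out cross-validation:
#' * `lda` — linear discriminant with pooled covariance (ridge-regularized
#'   fallback with a warning when the covariance is singular);
#' * `dtree` — binary classification tree grown with the entropy
#'   (information-gain) criterion;
#' * `ann` — feed-forward network with one hidden layer of `hidden`
#'   units trained by backpropagation (BFGS on the cross-entropy loss);
#'   accuracy is averaged over `ann_runs` random initializations.
#'
#' None of these are tuned; their settings are frozen here and logged in
#' the result.
#'
#' @param X Feature matrix (genes x features) or `feature_matrix`.
#' @param labels Per-gene labels.
#' @param method One of `"lda"`, `"dtree"`, `"ann"`.
#' @param ann_runs Number of averaged ANN restarts (default 30).
#' @param hidden Hidden-layer width for the ANN (default 5).
#' @param seed Seed for the ANN initializations.
#' @return List with `accuracy` (LOOCV), `method`, `settings`, and for
#'   non-averaged methods the per-gene `predicted` vector.
#' @export
baseline_classify <- function(X, labels, method = c("lda", "dtree", "ann"),
                              ann_runs = 30, hidden = 5, seed = 1) {
  method <- match.arg(method)
  X <- fm_values(X)
  y <- to_pm1(labels) > 0
  n <- nrow(X)
  if (sum(y) < 2L || sum(!y) < 2L)
    stop("need at least 2 genes per class")
  loo <- function(fit_predict) {
    vapply(seq_len(n), function(i)
      fit_predict(X[-i, , drop = FALSE], y[-i], X[i, , drop = FALSE]),
      logical(1))
  }
  if (method == "lda") {
    pred <- loo(function(Xt, yt, xnew) lda_predict(Xt, yt, xnew))
    acc <- mean(pred == y)
  } else if (method == "dtree") {
    pred <- loo(function(Xt, yt, xnew) {
      tree <- grow_tree(Xt, yt, depth = 0L)
      tree_predict(tree, xnew)
    })
    acc <- mean(pred == y)
  } else {
    set.seed(seed)
    init_seeds <- sample.int(1e6, ann_runs)
    accs <- vapply(init_seeds, function(s) {
      p <- loo(function(Xt, yt, xnew) ann_fit_predict(Xt, yt, xnew,
                                                      hidden = hidden,
                                                      seed = s))
      mean(p == y)
    }, numeric(1))
    acc <- mean(accs)
    pred <- NULL
  }
  list(accuracy = acc, method = method, predicted = pred,
       settings = list(ann_runs = ann_runs, hidden = hidden, seed = seed))
}

# pooled-covariance linear discriminant; ridge fallback when singular
lda_predict <- function(Xt, yt, xnew) {
  mu1 <- colMeans(Xt[yt, , drop = FALSE])
  mu0 <- colMeans(Xt[!yt, , drop = FALSE])
  n1 <- sum(yt); n0 <- sum(!yt)
  S <- (crossprod(sweep(Xt[yt, , drop = FALSE], 2, mu1)) +
          crossprod(sweep(Xt[!yt, , drop = FALSE], 2, mu0))) / (n1 + n0 - 2)
  Sinv <- tryCatch(solve(S), error = function(e) NULL)
  if (is.null(Sinv)) {
    warning("singular pooled covariance; ridge-regularized LDA used")
    Sinv <- solve(S + diag(1e-6 * mean(diag(S)) + 1e-12, ncol(S)))
  }
  w <- Sinv %*% (mu1 - mu0)
  thr <- 0.5 * sum((mu1 + mu0) * w) - log(n1 / n0)
  as.numeric(xnew %*% w) > thr
}

entropy <- function(y) {
  p <- mean(y)
  if (p == 0 || p == 1) return(0)
  -p * log2(p) - (1 - p) * log2(1 - p)
}

grow_tree <- function(X, y, depth, max_depth = 5L, min_n = 5L) {
  n <- length(y)
  if (depth >= max_depth || n < min_n || length(unique(y)) == 1L)
    return(list(leaf = TRUE, label = mean(y) > 0.5))
  h0 <- entropy(y)
  best <- list(gain = 0)
  for (j in seq_len(ncol(X))) {
    v <- sort(unique(X[, j]))
    if (length(v) < 2L) next
    for (thr in (v[-1] + v[-length(v)]) / 2) {
      left <- X[, j] <= thr
      gain <- h0 - (mean(left) * entropy(y[left]) +
                      mean(!left) * entropy(y[!left]))
      if (gain > best$gain + 1e-12)
        best <- list(gain = gain, j = j, thr = thr)
    }
  }
  if (best$gain <= 0) return(list(leaf = TRUE, label = mean(y) > 0.5))
  left <- X[, best$j] <= best$thr
  list(leaf = FALSE, j = best$j, thr = best$thr,
       left = grow_tree(X[left, , drop = FALSE], y[left], depth + 1L,
                        max_depth, min_n),
       right = grow_tree(X[!left, , drop = FALSE], y[!left], depth + 1L,
                         max_depth, min_n))
}

tree_predict <- function(node, xnew) {
  while (!node$leaf)
    node <- if (xnew[1, node$j] <= node$thr) node$left else node$right
  node$label
}

# one-hidden-layer logistic network trained by BFGS backpropagation
ann_fit_predict <- function(Xt, yt, xnew, hidden = 5, seed = 1,
                            maxit = 150, decay = 1e-4) {
  d <- ncol(Xt)
  n1 <- hidden * (d + 1)
  npar <- n1 + hidden + 1
  unpack <- function(th) list(
    W1 = matrix(th[1:n1], hidden, d + 1),
    w2 = th[(n1 + 1):npar])
  fwd <- function(th, X) {
    p <- unpack(th)
    H <- 1 / (1 + exp(-(cbind(1, X) %*% t(p$W1))))
    as.numeric(1 / (1 + exp(-(cbind(1, H) %*% p$w2))))
  }
  y01 <- as.numeric(yt)
  loss <- function(th) {
    p <- fwd(th, Xt)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -mean(y01 * log(p) + (1 - y01) * log(1 - p)) + decay * sum(th^2)
  }
  grad <- function(th) {
    pr <- unpack(th)
    A <- cbind(1, Xt)
    H <- 1 / (1 + exp(-(A %*% t(pr$W1))))
    Hb <- cbind(1, H)
    p <- as.numeric(1 / (1 + exp(-(Hb %*% pr$w2))))
    dout <- (p - y01) / length(y01)
    g2 <- as.numeric(crossprod(Hb, dout))
    dh <- (dout %*% t(pr$w2[-1])) * H * (1 - H)
    g1 <- t(dh) %*% A
    c(as.numeric(g1), g2) + 2 * decay * th
  }
  set.seed(seed)
  th0 <- rnorm(npar, sd = 0.5)
  fit <- stats::optim(th0, loss, grad, method = "BFGS",
                      control = list(maxit = maxit))
  fwd(fit$par, xnew) > 0.5
}
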