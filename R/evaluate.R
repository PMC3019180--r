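#' Confusion counts from predicted and true labels
#'
#' @param predicted Logical or "MSMG"/"not-MSMG" predictions.
#' @param actual Logical or "positive"/"negative" truth.
#' @return List of class `confusion_counts` with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(predicted, actual) {
  p <- if (is.logical(predicted)) predicted else predicted %in%
    c("MSMG", "positive", "1", "TRUE")
  a <- if (is.logical(actual)) actual else actual %in%
    c("MSMG", "positive", "1", "TRUE")
  structure(list(TP = sum(p & a), FP = sum(p & !a),
                 TN = sum(!p & !a), FN = sum(!p & a)),
            class = "confusion_counts")
}

#' Derived classification metrics
#'
#' Accuracy = (TP+TN)/(TP+TN+FP+FN), TPR = recall = TP/(TP+FN),
#' FPR = FP/(FP+TN), precision = TP/(TP+FP), F1 = 2TP/(2TP+FP+FN).
#' Components with a zero denominator are reported as `NA` (undefined),
#' never silently as 0.
#'
#' @param counts A `confusion_counts` or list with TP/FP/TN/FN.
#' @return List of class `eval_metrics`.
#' @examples
#' m <- confusion_metrics(list(TP = 37, FP = 3, TN = 67, FN = 9))
#' round(m$accuracy, 2)  # 0.9
#' @export
confusion_metrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  total <- TP + FP + TN + FN
  if (total == 0) stop("all confusion counts are zero")
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(
    accuracy = (TP + TN) / total,
    TPR = safe_div(TP, TP + FN),
    FPR = safe_div(FP, FP + TN),
    precision = safe_div(TP, TP + FP),
    recall = safe_div(TP, TP + FN),
    F1 = safe_div(2 * TP, 2 * TP + FP + FN)),
    class = "eval_metrics")
}

# held-out decision scores from leave-one-out over a fixed Gram matrix
loocv_scores_kernel <- function(K, y, C = 1, tol = 1e-4) {
  n <- length(y)
  vapply(seq_len(n), function(i) {
    yt <- y[-i]
    if (length(unique(yt)) < 2L)
      stop("a training fold lost one class entirely (n_class = 1)")
    m <- train_svm(K[-i, -i, drop = FALSE], yt, C = C, tol = tol,
                   check_psd = FALSE)
    as.numeric(K[i, -i, drop = FALSE] %*% m$coef + m$b)
  }, numeric(1))
}

#' Leave-one-out cross-validation of a kernel SVM
#'
#' Runs the n-iteration LOOCV protocol: train on n-1 genes, score the
#' one left out, aggregate held-out predictions into one set of
#' confusion counts.  For the RBF kernel the width sigma can be
#' selected three ways: `"nested"` (default) runs an honest inner
#' LOOCV within every training fold and may pick a different sigma per
#' fold; `"flat"` selects the single sigma maximizing the plain LOOCV
#' accuracy (the optimistic single-loop protocol) and reports that run;
#' `"none"` uses the supplied `sigma` as is.  Grid ties are broken
#' toward the smallest sigma.
#'
#' @param X Feature matrix (genes x features) or `feature_matrix`.
#' @param labels Per-gene labels (+1/-1 or "positive"/"negative").
#' @param spec A [kernel_spec()].
#' @param C Soft-margin cost.
#' @param selection Sigma-selection protocol (RBF only).
#' @param grid Candidate sigmas for selection (default
#'   `sigma_grid(n_points = 7)`).
#' @return List of class `loocv_result`: `confusion`, `metrics`,
#'   per-gene `scores`/`predicted`, selected `sigma` (or per-fold
#'   vector), `n_folds`.
#' @export
loocv_svm <- function(X, labels, spec = kernel_spec("rbf"), C = 1,
                      selection = c("nested", "flat", "none"),
                      grid = sigma_grid(n_points = 7)) {
  selection <- match.arg(selection)
  X <- fm_values(X)
  y <- to_pm1(labels)
  n <- nrow(X)
  if (n < 4L) stop("LOOCV needs at least 4 samples")
  if (length(unique(y)) < 2L) stop("both classes must be present")

  needs_sigma <- spec$family == "rbf" && is.null(spec$sigma)
  if (!needs_sigma || selection == "none") {
    if (spec$family == "rbf" && is.null(spec$sigma))
      stop("selection \"none\" requires sigma in the kernel spec")
    K <- checked_kernel(X, spec)
    scores <- loocv_scores_kernel(K, y, C)
    sigma_used <- spec$sigma
  } else {
    Ks <- lapply(grid, function(s)
      checked_kernel(X, kernel_spec("rbf", sigma = s)))
    if (selection == "flat") {
      accs <- vapply(Ks, function(K)
        mean((loocv_scores_kernel(K, y, C) > 0) == (y > 0)), numeric(1))
      # first maximum = smallest sigma on ties; epsilon absorbs FP noise
      best <- which(accs >= max(accs) - 1e-12)[1]
      scores <- loocv_scores_kernel(Ks[[best]], y, C)
      sigma_used <- grid[best]
    } else {
      scores <- numeric(n)
      sigma_used <- numeric(n)
      for (i in seq_len(n)) {
        yt <- y[-i]
        if (length(unique(yt)) < 2L)
          stop("a training fold lost one class entirely (n_class = 1)")
        inner_acc <- vapply(Ks, function(K) {
          si <- loocv_scores_kernel(K[-i, -i, drop = FALSE], yt, C)
          mean((si > 0) == (yt > 0))
        }, numeric(1))
        bi <- which(inner_acc >= max(inner_acc) - 1e-12)[1]
        m <- train_svm(Ks[[bi]][-i, -i, drop = FALSE], yt, C = C,
                       check_psd = FALSE)
        scores[i] <- as.numeric(Ks[[bi]][i, -i, drop = FALSE] %*% m$coef + m$b)
        sigma_used[i] <- grid[bi]
      }
    }
  }
  predicted <- scores > 0
  cc <- confusion_counts(predicted, y > 0)
  structure(list(confusion = cc, metrics = confusion_metrics(cc),
                 scores = setNames(scores, rownames(X)),
                 predicted = predicted, sigma = sigma_used,
                 selection = selection, n_folds = n, C = C,
                 family = spec$family),
            class = "loocv_result")
}

fm_values <- function(X) {
  if (inherits(X, "feature_matrix")) X$values else as.matrix(X)
}

checked_kernel <- function(X, spec) {
  K <- compute_kernel(X, spec = spec)
  ok <- kernel_is_psd(K)
  if (!ok)
    stop(sprintf("Gram matrix is not PSD (min eigenvalue %.3e)",
                 attr(ok, "min_eigenvalue")))
  K
}

#' ROC curve from held-out scores
#'
#' Staircase construction sweeping the decision threshold over the
#' observed scores; equal scores collapse into a single threshold step.
#'
#' @param scores Decision scores.
#' @param labels Truth (+1/-1 or logical or "positive"/"negative").
#' @return Data frame with `FPR` and `TPR`, monotone nondecreasing,
#'   with an `auc` attribute (trapezoid rule).
#' @export
roc_curve <- function(scores, labels) {
  truth <- to_pm1(labels) > 0
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; truth <- truth[o]
  keep <- !duplicated(s, fromLast = TRUE)  # last index of each tie block
  tp <- cumsum(truth)[keep]
  fp <- cumsum(!truth)[keep]
  P <- sum(truth); N <- sum(!truth)
  curve <- data.frame(FPR = c(0, fp / N), TPR = c(0, tp / P))
  auc <- sum(diff(curve$FPR) * (utils::head(curve$TPR, -1) +
                                  utils::tail(curve$TPR, -1)) / 2)
  attr(curve, "auc") <- auc
  curve
}

#' Three-fold cross-validated ROC/AUC
#'
#' Stratified (per-class, seeded) split into three folds; each fold is
#' held out once while the SVM trains on the other two, and its ROC is
#' built from the held-out decision scores.  The reported AUC is the
#' average of the three per-fold trapezoid AUCs.
#'
#' @param X Feature matrix or `feature_matrix`.
#' @param labels Per-gene labels.
#' @param spec A [kernel_spec()]; an RBF spec without `sigma` uses the
#'   median-closest-negative-distance heuristic inside each training
#'   split.
#' @param C Soft-margin cost.
#' @param seed Seed controlling fold assignment.
#' @return List of class `roc_result`: `folds` (list with `curve` and
#'   `auc`), `auc_mean`, fold assignment.
#' @export
roc_threefold <- function(X, labels, spec = kernel_spec("rbf"), C = 1,
                          seed = 1) {
  X <- fm_values(X)
  y <- to_pm1(labels)
  n <- nrow(X)
  if (n < 6L) stop("three-fold ROC needs at least 6 samples")
  set.seed(seed)
  fold <- integer(n)
  for (cl in c(1, -1)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(1:3, length(idx))
  }
  folds <- lapply(1:3, function(f) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L)
      stop("a fold lacks one class after stratification")
    sp <- spec
    if (sp$family == "rbf" && is.null(sp$sigma))
      sp$sigma <- median_sigma(X[tr & y > 0, , drop = FALSE],
                               X[tr & y < 0, , drop = FALSE])
    K <- compute_kernel(X[tr, , drop = FALSE], spec = sp)
    m <- train_svm(K, y[tr], C = C, check_psd = FALSE)
    Kt <- compute_kernel(X[!tr, , drop = FALSE], X[tr, , drop = FALSE], sp)
    sc <- as.numeric(Kt %*% m$coef + m$b)
    curve <- roc_curve(sc, y[!tr])
    list(curve = curve, auc = attr(curve, "auc"))
  })
  structure(list(folds = folds,
                 auc_mean = mean(vapply(folds, `[[`, numeric(1), "auc")),
                 fold = fold),
            class = "roc_result")
}

#' Spearman rank correlation (Pearson on average ranks)
#'
#' @param u,v Equal-length numeric vectors, length >= 3.
#' @return Correlation in \[-1, 1\]; `NA` with a warning if either
#'   input is constant.
#' @export
rank_correlation <- function(u, v) {
  if (length(u) != length(v)) stop("inputs must have equal length")
  if (length(u) < 3L) stop("need at least 3 observations")
  ru <- rank(u, ties.method = "average")
  rv <- rank(v, ties.method = "average")
  if (sd(ru) == 0 || sd(rv) == 0) {
    warning("rank correlation undefined for a constant input")
    return(NA_real_)
  }
  sum((ru - mean(ru)) * (rv - mean(rv))) /
    sqrt(sum((ru - mean(ru))^2) * sum((rv - mean(rv))^2))
}

#' One-sided overlap enrichment (Fisher's exact / hypergeometric)
#'
#' Upper-tail probability of observing at least the actual overlap
#' between two gene sets drawn from a universe of the given size.
#'
#' @param listA,listB Character vectors (gene sets).
#' @param universe_size Size of the common universe.
#' @return P-value in (0, 1\].
#' @export
fisher_overlap <- function(listA, listB, universe_size) {
  listA <- unique(listA); listB <- unique(listB)
  if (length(union(listA, listB)) > universe_size)
    stop("universe smaller than the union of the two lists")
  ov <- length(intersect(listA, listB))
  phyper(ov - 1, length(listA), universe_size - length(listA),
         length(listB), lower.tail = FALSE)
}
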