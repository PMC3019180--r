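#' SVM recursive feature elimination
#'
#' Ranks features by discriminatory capability: in each round an SVM is
#' trained on the remaining features and the `step` features with the
#' smallest elimination criterion are dropped; the reversed elimination
#' order is the ranking (best-discriminating first).
#'
#' The criterion follows the classic kernel-space recipe: for the
#' linear kernel, the squared primal weight w_j^2 with
#' w = sum_i alpha_i y_i x_i; for nonlinear kernels, the margin-change
#' criterion |W^2(alpha) - W^2_(-j)(alpha)| where
#' W^2(alpha) = sum_{i,k} alpha_i alpha_k y_i y_k K(x_i, x_k) and
#' W^2_(-j) recomputes the kernel with feature j removed while keeping
#' the dual coefficients fixed.  Ties are broken by eliminating the
#' lower column index first.  Hyperparameters (sigma, C) are frozen for
#' all rounds; sigma defaults to the median-distance heuristic on the
#' full feature set when the RBF spec carries none.
#'
#' @param X Feature matrix (genes x features, >= 2 columns) or
#'   `feature_matrix`.
#' @param labels Per-gene labels, both classes present.
#' @param spec A [kernel_spec()].
#' @param C Soft-margin cost.
#' @param step Features removed per round (default 1; the final round
#'   removes whatever remains, ranked by criterion).
#' @return Object of class `feature_ranking`: data frame `ranking`
#'   (`rank`, `feature`, `criterion`, `round`) and the frozen `sigma`.
#' @export
svm_rfe <- function(X, labels, spec = kernel_spec("linear"), C = 1,
                    step = 1) {
  X <- fm_values(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- to_pm1(labels)
  if (ncol(X) < 2L) stop("need at least 2 features")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (step < 1L) stop("step must be >= 1")
  if (spec$family == "rbf" && is.null(spec$sigma))
    spec$sigma <- median_sigma(X[y > 0, , drop = FALSE],
                               X[y < 0, , drop = FALSE])

  remaining <- seq_len(ncol(X))
  eliminated <- integer(0)
  crit_log <- numeric(0)
  round_log <- integer(0)
  round_i <- 0L
  while (length(remaining) > 0L) {
    round_i <- round_i + 1L
    crit <- rfe_criterion(X[, remaining, drop = FALSE], y, spec, C)
    # order by criterion; ties eliminate the lower original column first
    ord <- order(crit, remaining)
    k <- min(step, length(remaining))
    if (length(remaining) <= step) k <- length(remaining)
    drop_local <- ord[seq_len(k)]
    eliminated <- c(eliminated, remaining[drop_local])
    crit_log <- c(crit_log, crit[drop_local])
    round_log <- c(round_log, rep(round_i, k))
    remaining <- remaining[-drop_local]
  }
  ranking <- data.frame(rank = seq_along(eliminated),
                        feature = colnames(X)[rev(eliminated)],
                        criterion = rev(crit_log),
                        round = rev(round_log),
                        stringsAsFactors = FALSE)
  structure(list(ranking = ranking, spec = spec, C = C, step = step),
            class = "feature_ranking")
}

rfe_criterion <- function(Xs, y, spec, C) {
  K <- compute_kernel(Xs, spec = spec)
  m <- train_svm(K, y, C = C, check_psd = FALSE)
  cy <- m$coef                        # alpha_i * y_i
  if (spec$family == "linear") {
    w <- as.numeric(crossprod(Xs, cy))
    return(w^2)
  }
  outer_cy <- tcrossprod(cy)
  W2 <- sum(outer_cy * K)
  L <- tcrossprod(Xs)                 # shared linear Gram
  vapply(seq_len(ncol(Xs)), function(j) {
    xj <- Xs[, j]
    if (spec$family == "polynomial") {
      Kj <- (L - tcrossprod(xj) + 1)^spec$degree
    } else {                          # rbf: remove feature j from |x-y|^2
      dj <- outer(xj, xj, "-")^2
      Kj <- K * exp(dj / (2 * spec$sigma^2))
    }
    abs(W2 - sum(outer_cy * Kj))
  }, numeric(1))
}

#' Top-k report of a feature ranking
#' @param ranking A `feature_ranking`.
#' @param k Number of features (default 20).
#' @return Character vector of the top `k` feature names.
#' @export
top_features <- function(ranking, k = 20) {
  stopifnot(inherits(ranking, "feature_ranking"))
  utils::head(ranking$ranking$feature, k)
}

#' Overlap between the top-k sets of two rankings
#'
#' @param rankA,rankB `feature_ranking` objects or character vectors of
#'   ranked feature names (no duplicates).
#' @param k Top-set size (default 20).
#' @param universe Total number of features the rankings are drawn from
#'   (defaults to the ranking length).
#' @return List with `overlap` (count), `features` (shared names) and
#'   `p_value` (one-sided Fisher's exact enrichment).
#' @export
ranking_overlap <- function(rankA, rankB, k = 20, universe = NULL) {
  get_names <- function(r)
    if (inherits(r, "feature_ranking")) r$ranking$feature else as.character(r)
  a <- get_names(rankA); b <- get_names(rankB)
  if (anyDuplicated(a) || anyDuplicated(b))
    stop("rankings must not contain duplicated features")
  universe <- universe %||% max(length(a), length(b))
  if (k > universe) stop("k exceeds the feature universe")
  ta <- utils::head(a, k); tb <- utils::head(b, k)
  shared <- intersect(ta, tb)
  list(overlap = length(shared), features = shared,
       p_value = fisher_overlap(ta, tb, universe))
}
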