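#' Train a soft-margin SVM on a precomputed kernel
#'
#' Solves the dual problem by sequential minimal optimization directly
#' on the Gram matrix, so any kernel — including the F1-weighted
#' two-data-type combination — can be used without access to explicit
#' coordinates.
#'
#' @param K Symmetric PSD Gram matrix over the training genes
#'   (row/col names are taken as gene ids when present).
#' @param y Labels: a vector of +1/-1, or a logical/factor coerced so
#'   the positive class is +1.
#' @param C Soft-margin cost (default 1).
#' @param tol KKT violation tolerance of the solver (default 1e-4).
#' @param max_iter Iteration cap.
#' @param check_psd Verify PSD-ness of `K` before solving (default
#'   `TRUE`; internal cross-validation loops disable it after checking
#'   the full Gram once).
#' @return Object of class `svm_model`: gene ids, dual coefficients
#'   `alpha` (in `[0, C]`), signed coefficients `coef = alpha * y`,
#'   bias `b`, and the labels.  Decision scores for new genes are
#'   `K_test %*% coef + b`.
#' @export
train_svm <- function(K, y, C = 1, tol = 1e-4, max_iter = 200000L,
                      check_psd = TRUE) {
  y <- to_pm1(y)
  n <- length(y)
  if (!all(dim(K) == n)) stop("kernel/label dimensions differ")
  if (length(unique(y)) < 2L)
    stop("training labels contain a single class")
  if (C <= 0) stop("C must be positive")
  if (check_psd) {
    ok <- kernel_is_psd(K)
    if (!ok)
      stop(sprintf("kernel is not PSD (min eigenvalue %.3e)",
                   attr(ok, "min_eigenvalue")))
  }
  sol <- smo_solve(K, as.numeric(y), C, tol, as.integer(max_iter))
  if (!sol$converged)
    warning("SMO did not converge within max_iter; results may be inexact")
  structure(list(gene_ids = rownames(K), alpha = sol$alpha,
                 coef = sol$alpha * y, b = sol$b, y = y, C = C,
                 iterations = sol$iterations),
            class = "svm_model")
}

to_pm1 <- function(y) {
  if (is.numeric(y)) {
    if (!all(y %in% c(-1, 1))) stop("numeric labels must be +1/-1")
    return(as.numeric(y))
  }
  if (is.logical(y)) return(ifelse(y, 1, -1))
  y <- as.character(y)
  pos <- c("positive", "MSMG", "1", "TRUE", "+1")
  ifelse(y %in% pos, 1, -1)
}

#' Decision scores and labels for new genes
#'
#' @param object A trained `svm_model`.
#' @param K_test Cross-kernel matrix, test genes x training genes, with
#'   columns in training order (checked against stored gene ids when
#'   both carry names).
#' @param ... Unused.
#' @return Data frame with `gene_id`, `score` and `label`
#'   (`"MSMG"` iff score > 0).
#' @export
predict.svm_model <- function(object, K_test, ...) {
  K_test <- rbind(K_test)
  if (ncol(K_test) != length(object$coef))
    stop("test kernel columns do not match training size")
  if (!is.null(colnames(K_test)) && !is.null(object$gene_ids) &&
      !identical(colnames(K_test), object$gene_ids))
    stop("test kernel columns are not aligned with training gene order")
  score <- as.numeric(K_test %*% object$coef + object$b)
  data.frame(gene_id = rownames(K_test) %||% seq_along(score),
             score = score,
             label = ifelse(score > 0, "MSMG", "not-MSMG"),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fold-change baseline classifier
#'
#' Calls a gene MSMG iff its ES-to-EB expression ratio strictly exceeds
#' one — the "is it simply ES-specific?" straw man.
#'
#' @param es_expr,eb_expr Positive expression values per gene.
#' @param gene_ids Optional ids.
#' @return Data frame with `gene_id`, `score` (the ratio) and `label`.
#' @export
fold_change_classifier <- function(es_expr, eb_expr, gene_ids = NULL) {
  if (any(eb_expr <= 0)) stop("EB expression must be positive")
  r <- es_expr / eb_expr
  data.frame(gene_id = gene_ids %||% seq_along(r), score = r,
             label = ifelse(r > 1, "MSMG", "not-MSMG"),
             stringsAsFactors = FALSE)
}

#' Serialize / restore a trained SVM
#'
#' @param model An `svm_model`.
#' @param path JSON file path.
#' @return `save_svm_model` the path invisibly; `load_svm_model` the
#'   restored model.
#' @export
save_svm_model <- function(model, path) {
  stopifnot(inherits(model, "svm_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_svm_model
#' @export
load_svm_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$y <- as.numeric(m$y)
  structure(m, class = "svm_model")
}
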