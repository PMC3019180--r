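#' Kernel specification
#'
#' @param family `"linear"` (K = X.Y), `"polynomial"`
#'   ((X.Y + 1)^degree), or `"rbf"` (exp(-|X-Y|^2 / 2 sigma^2)).
#' @param degree Polynomial degree (default 3).
#' @param sigma RBF width; must be positive when supplied.
#' @param gamma Alias parameterization for the RBF width,
#'   gamma = 1 / (2 sigma^2); supply one of `sigma`/`gamma`.
#' @return Object of class `kernel_spec`.
#' @export
kernel_spec <- function(family = c("linear", "polynomial", "rbf"),
                        degree = 3, sigma = NULL, gamma = NULL) {
  family <- match.arg(family)
  if (!is.null(gamma)) {
    if (!is.null(sigma)) stop("supply only one of sigma and gamma")
    if (gamma <= 0) stop("parameter error: gamma must be positive")
    sigma <- 1 / sqrt(2 * gamma)
  }
  if (!is.null(sigma) && sigma <= 0)
    stop("parameter error: sigma must be positive")
  structure(list(family = family, degree = degree, sigma = sigma),
            class = "kernel_spec")
}

sq_dist <- function(Xa, Xb) {
  d2 <- outer(rowSums(Xa^2), rowSums(Xb^2), "+") - 2 * tcrossprod(Xa, Xb)
  pmax(d2, 0)
}

#' Compute a (cross-)kernel matrix
#'
#' @param Xa,Xb Numeric feature matrices with matching columns; `Xb`
#'   defaults to `Xa`, giving the symmetric Gram matrix.
#' @param spec A [kernel_spec()]; RBF requires `sigma` set.
#' @return `nrow(Xa) x nrow(Xb)` matrix.  For `Xb = Xa` the result is
#'   exactly symmetric and the RBF diagonal is exactly 1.
#' @export
compute_kernel <- function(Xa, Xb = NULL, spec = kernel_spec("linear")) {
  Xa <- as.matrix(Xa)
  symmetric <- is.null(Xb)
  Xb <- if (symmetric) Xa else as.matrix(Xb)
  if (ncol(Xa) != ncol(Xb)) stop("feature dimensions differ")
  K <- switch(spec$family,
    linear = tcrossprod(Xa, Xb),
    polynomial = (tcrossprod(Xa, Xb) + 1)^spec$degree,
    rbf = {
      if (is.null(spec$sigma)) stop("parameter error: rbf needs sigma")
      d2 <- sq_dist(Xa, Xb)
      if (symmetric) diag(d2) <- 0
      exp(-d2 / (2 * spec$sigma^2))
    })
  if (symmetric) K <- (K + t(K)) / 2
  dimnames(K) <- list(rownames(Xa), rownames(Xb))
  K
}

#' Median closest-opposite-class distance heuristic for the RBF width
#'
#' For each positive sample, the Euclidean distance to its closest
#' negative sample is computed; sigma is the median of these minima.
#'
#' @param X_pos,X_neg Feature matrices for the two classes (non-empty).
#' @return Positive scalar sigma.
#' @export
median_sigma <- function(X_pos, X_neg) {
  if (NROW(X_pos) == 0L || NROW(X_neg) == 0L)
    stop("both classes must be non-empty")
  d2 <- sq_dist(as.matrix(X_pos), as.matrix(X_neg))
  s <- median(sqrt(apply(d2, 1, min)))
  if (s == 0) stop("degenerate sigma: median closest-negative distance is 0")
  s
}

#' Log-uniform grid of candidate RBF widths
#'
#' @param lo,hi Grid endpoints (default 1e-2 to 1e1, the search range
#'   used for width selection by cross-validation).
#' @param n_points Number of grid points (endpoints included).
#' @return Numeric vector of length `n_points`.
#' @examples
#' sigma_grid(n_points = 4)  # 0.01 0.1 1 10
#' @export
sigma_grid <- function(lo = 1e-2, hi = 1e1, n_points = 7) {
  if (n_points == 1L) return(lo)
  if (lo >= hi) stop("lo must be smaller than hi")
  exp(seq(log(lo), log(hi), length.out = n_points))
}

#' F1-weighted combination of two data-type kernels
#'
#' Combines the expression-data and ChIP-data Gram matrices as
#' `K = f1_m * Km + f1_c * Kc`, weighting each data type by the F1
#' score its single-type classifier achieves, so the more reliable data
#' type dominates the combined geometry.  A nonnegative combination of
#' PSD matrices is PSD.
#'
#' @param Km,Kc Gram matrices over the same genes in the same order.
#' @param f1_m,f1_c Nonnegative weights (F1 scores in \[0, 1\]).
#' @return Combined Gram matrix.
#' @export
weighted_kernel <- function(Km, Kc, f1_m, f1_c) {
  if (!all(dim(Km) == dim(Kc))) stop("kernel dimensions differ")
  if (!is.null(rownames(Km)) && !is.null(rownames(Kc)) &&
      !identical(rownames(Km), rownames(Kc)))
    stop("gene order differs between kernels")
  if (f1_m < 0 || f1_c < 0) stop("weights must be non-negative")
  f1_m * Km + f1_c * Kc
}

#' Check a Gram matrix for symmetry and positive semi-definiteness
#'
#' @param K Square matrix.
#' @param tol_factor PSD tolerance: the minimum eigenvalue must be at
#'   least `-tol_factor * trace(K)`.
#' @return `TRUE`/`FALSE` with attributes `min_eigenvalue` and
#'   `symmetric`.
#' @export
kernel_is_psd <- function(K, tol_factor = 1e-8) {
  sym <- max(abs(K - t(K))) <= 1e-10 * max(1, max(abs(K)))
  ev <- eigen((K + t(K)) / 2, symmetric = TRUE, only.values = TRUE)$values
  ok <- sym && min(ev) >= -tol_factor * sum(diag(K))
  structure(ok, min_eigenvalue = min(ev), symmetric = sym)
}
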