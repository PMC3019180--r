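#' Log-transform and unit-scale an expression vector
#'
#' Maps a gene's raw expression profile E to
#' \deqn{X_i = \log_2(E_i) / \sqrt{\sum_i \log_2(E_i)^2},}
#' so every non-degenerate gene vector has unit Euclidean norm — the
#' classic preprocessing for SVMs on expression profiles.
#'
#' @param E Strictly positive numeric vector.
#' @param pseudocount Optional non-negative value added to `E` before
#'   the log (default 0, i.e. non-positive input is rejected loudly).
#' @return Numeric vector of the same length with unit Euclidean norm.
#' @examples
#' normalize_expression(c(2, 4, 16))  # (1,2,4)/sqrt(21)
#' @export
normalize_expression <- function(E, pseudocount = 0) {
  E <- E + pseudocount
  if (any(E <= 0))
    stop("value error: expression values must be strictly positive")
  l <- log2(E)
  nrm <- sqrt(sum(l^2))
  if (nrm == 0)
    stop("degenerate expression vector: all values equal 1 after log")
  l / nrm
}

peak_centers <- function(peaks) (peaks$start + peaks$end) / 2

#' Binary TSS-proximal binding indicator
#'
#' @param peaks Peak data frame (`chrom`, `start`, `end`, `intensity`)
#'   for one TF; may have zero rows.
#' @param gene One-row gene annotation (`chrom`, `tss`).
#' @param window Half-width in bp; a gene scores 1 iff at least one
#'   peak center lies within `tss +/- window`, bounds inclusive.
#' @return Integer 0 or 1.
#' @export
binary_binding <- function(peaks, gene, window = 1000) {
  if (window <= 0) stop("window must be positive")
  if (NROW(peaks) == 0L) return(0L)
  same <- peaks$chrom == gene$chrom
  d <- abs(peak_centers(peaks)[same] - gene$tss)
  as.integer(any(d <= window))
}

#' Distance-decay continuous binding score
#'
#' Sums peak intensities weighted by exponential decay in the
#' TSS-to-peak-center distance:
#' \deqn{a = \sum_k g_k e^{-d_k / d_0}.}
#' Additive over peaks and strictly decreasing in each distance; the
#' decay constant `d0` sets the bp scale over which binding "counts".
#'
#' @param peaks Peak data frame for one TF (possibly empty).
#' @param gene One-row gene annotation (`chrom`, `tss`).
#' @param d0 Decay constant in bp (default 5000).
#' @return Non-negative scalar.
#' @export
continuous_binding <- function(peaks, gene, d0 = 5000) {
  if (d0 <= 0) stop("d0 must be positive")
  if (NROW(peaks) == 0L) return(0)
  if (any(peaks$intensity < 0))
    stop("value error: peak intensities must be non-negative")
  same <- peaks$chrom == gene$chrom
  d <- abs(peak_centers(peaks)[same] - gene$tss)
  sum(peaks$intensity[same] * exp(-d / d0))
}

#' Quantile normalization against the mean-quantile reference
#'
#' Forces the columns of a matrix to share one empirical distribution:
#' each column's sorted values are replaced by the across-column mean of
#' sorted values, mapped back through average ranks (ties receive the
#' mean of the reference values they span).
#'
#' Tied values can be resolved two ways: `"average"` gives every tied
#' entry the mean of the reference values its rank block spans (so ties
#' stay ties), while `"first"` maps sorted positions to the reference
#' directly (occurrence order breaks ties), which preserves the
#' reference multiset in every column exactly.
#'
#' @param M Numeric matrix with at least 2 rows.
#' @param ties Tie policy, `"average"` (default) or `"first"`.
#' @return Matrix of the same shape sharing the mean-quantile reference
#'   distribution across columns.
#' @export
quantile_normalize <- function(M, ties = c("average", "first")) {
  ties <- match.arg(ties)
  if (nrow(M) < 2L) stop("quantile normalization needs at least 2 rows")
  ref <- rowMeans(apply(M, 2, sort))
  out <- apply(M, 2, function(col) {
    if (ties == "average") {
      r <- rank(col, ties.method = "average")
      (ref[floor(r)] + ref[ceiling(r)]) / 2
    } else {
      res <- numeric(length(col))
      res[order(col)] <- ref
      res
    }
  })
  dimnames(out) <- dimnames(M)
  out
}

#' Transform a raw binding-score matrix
#'
#' Entrywise `log2(a + 1)` (the pseudocount accommodates unbound genes
#' with a = 0) followed by [quantile_normalize()] across the TF columns
#' with `ties = "first"`, so the 12 TF columns share their value
#' multiset exactly even through the large tie block of unbound genes.
#'
#' @param A Non-negative matrix, genes x TFs.
#' @return Transformed matrix of the same shape.
#' @export
transform_binding_matrix <- function(A) {
  if (any(A < 0)) stop("binding scores must be non-negative")
  quantile_normalize(log2(A + 1), ties = "first")
}

#' Build the ChIP feature block
#'
#' @param genes Gene annotation data frame.
#' @param peaks Named list of per-TF peak data frames.
#' @param mode `"binary"` (presence within `window` of the TSS) or
#'   `"continuous"` (distance-decay score, log-transformed and
#'   quantile-normalized).
#' @param window,d0 Mode parameters in bp.
#' @return Numeric matrix, genes x TFs.
#' @export
build_chip_features <- function(genes, peaks, mode = c("binary", "continuous"),
                                window = 1000, d0 = 5000) {
  mode <- match.arg(mode)
  fun <- if (mode == "binary") {
    function(p, g) binary_binding(p, g, window)
  } else {
    function(p, g) continuous_binding(p, g, d0)
  }
  A <- vapply(peaks, function(p) {
    vapply(seq_len(nrow(genes)), function(i) as.numeric(fun(p, genes[i, ])),
           numeric(1))
  }, numeric(nrow(genes)))
  dimnames(A) <- list(genes$gene_id, names(peaks))
  if (mode == "continuous") A <- transform_binding_matrix(A)
  A
}

#' Assemble a feature matrix with provenance
#'
#' Concatenates the scaled expression block and/or a ChIP block into the
#' per-gene feature matrix used for kernel computation.  Column counts
#' by mode: `micro` 79, `chip_binary`/`chip_contin` 12,
#' `combined_binary`/`combined_contin` 91.
#'
#' @param expr_X Scaled expression matrix (genes x 79) or `NULL`.
#' @param chip ChIP feature matrix (genes x 12) or `NULL`.
#' @param mode One of `micro`, `chip_binary`, `chip_contin`,
#'   `combined_binary`, `combined_contin`.
#' @return An object of class `feature_matrix`: list with `values`,
#'   `gene_ids` and a `feature_info` data frame (`name`, `source`,
#'   `mode`).
#' @export
assemble_features <- function(expr_X = NULL, chip = NULL,
                              mode = c("micro", "chip_binary", "chip_contin",
                                       "combined_binary", "combined_contin")) {
  mode <- match.arg(mode)
  need_expr <- mode %in% c("micro", "combined_binary", "combined_contin")
  need_chip <- mode != "micro"
  if (need_expr && is.null(expr_X)) stop("mode ", mode, " needs expression")
  if (need_chip && is.null(chip)) stop("mode ", mode, " needs ChIP features")
  if (need_expr && need_chip &&
      !identical(rownames(expr_X), rownames(chip)))
    stop("alignment error: gene sets differ between data types")
  chip_mode <- if (grepl("binary", mode)) "chip-binary" else "chip-continuous"
  blocks <- list()
  info <- list()
  if (need_expr) {
    blocks$expr <- expr_X
    info$expr <- data.frame(name = colnames(expr_X), source = "expression",
                            mode = "expression", stringsAsFactors = FALSE)
  }
  if (need_chip) {
    blocks$chip <- chip
    info$chip <- data.frame(name = paste0("chip_", colnames(chip)),
                            source = "chip", mode = chip_mode,
                            stringsAsFactors = FALSE)
  }
  values <- do.call(cbind, unname(blocks))
  feature_info <- do.call(rbind, unname(info))
  colnames(values) <- feature_info$name
  if (anyNA(values)) stop("feature matrix contains missing values")
  structure(list(values = values, gene_ids = rownames(values),
                 feature_info = feature_info, mode = mode),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d genes x %d features (mode %s)\n",
              nrow(x$values), ncol(x$values), x$mode))
  tab <- table(x$feature_info$source)
  cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Build a feature matrix straight from simulated or loaded inputs
#'
#' Convenience wrapper: applies [normalize_expression()] per gene,
#' builds the requested ChIP block, and assembles.
#'
#' @param genes,expression,peaks Study components (e.g. from
#'   [simulate_study()] or the fixture readers).
#' @param mode Feature mode, see [assemble_features()].
#' @param window,d0 ChIP parameters (bp).
#' @param pseudocount Passed to [normalize_expression()].
#' @return A `feature_matrix`.
#' @export
build_feature_matrix <- function(genes, expression, peaks,
                                 mode = "combined_contin",
                                 window = 1000, d0 = 5000, pseudocount = 0) {
  expr_X <- NULL
  chip <- NULL
  if (mode != "micro") {
    chip_mode <- if (grepl("binary", mode)) "binary" else "continuous"
    chip <- build_chip_features(genes, peaks, chip_mode, window, d0)
  }
  if (mode %in% c("micro", "combined_binary", "combined_contin")) {
    expr_X <- t(apply(expression, 1, normalize_expression,
                      pseudocount = pseudocount))
    dimnames(expr_X) <- dimnames(expression)
  }
  assemble_features(expr_X, chip, mode)
}

# column subsets of a combined feature matrix by data type
feature_columns <- function(fm, source) {
  which(fm$feature_info$source == source)
}
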