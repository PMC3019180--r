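#' Train a full MSMG classifier pipeline
#'
#' Wires feature selection by data type, RBF-width selection and SVM
#' training into one object that can score unseen genes.  Data-type
#' strategies:
#' * `micro` — expression features only (79 columns);
#' * `chip` — ChIP features only (12 columns, binary or continuous
#'   depending on how `fm` was built);
#' * `simple` — concatenation of both blocks (91 columns, one kernel);
#' * `weight` — one kernel per data type, combined as
#'   `F1_m * Km + F1_c * Kc` where each F1 is the training-set LOOCV F1
#'   of that data type's own single-type classifier.
#'
#' @param fm A combined `feature_matrix` (91 columns) from
#'   [build_feature_matrix()]; `micro` also accepts a 79-column one.
#' @param labels Per-gene labels aligned with `fm`.
#' @param mode Data-type strategy (above).
#' @param family Kernel family: `"linear"`, `"poly"` or `"RBF"`.
#' @param C Soft-margin cost (default 1).
#' @param sigma Optional fixed RBF width; when `NULL` the width is
#'   selected on the training set by LOOCV over `grid` (flat protocol,
#'   smallest sigma on ties).
#' @param grid Candidate sigmas.
#' @return Object of class `msmg_classifier` with the trained SVM, the
#'   stored training feature blocks, selected widths, data-type weights
#'   (weight mode) and the training LOOCV result(s).
#' @export
msmg_train <- function(fm, labels, mode = c("simple", "micro", "chip",
                                            "weight"),
                       family = c("RBF", "linear", "poly"), C = 1,
                       sigma = NULL, grid = sigma_grid(n_points = 7)) {
  mode <- match.arg(mode)
  family <- match.arg(family)
  spec0 <- family_spec(family, sigma)
  blocks <- mode_blocks(fm, mode)
  y <- to_pm1(labels)

  if (mode != "weight") {
    X <- do.call(cbind, blocks)
    fit <- fit_block(X, y, spec0, C, grid)
    svm <- fit$model
    specs <- list(fit$spec)
    weights <- NULL
    cv <- fit$cv
  } else {
    fits <- lapply(blocks, fit_block, y = y, spec = spec0, C = C,
                   grid = grid)
    weights <- vapply(fits, function(f) {
      f1 <- f$cv$metrics$F1
      if (is.na(f1)) 0 else f1
    }, numeric(1))
    Kw <- weighted_kernel(fits[[1]]$K, fits[[2]]$K, weights[1], weights[2])
    svm <- train_svm(Kw, y, C = C, check_psd = FALSE)
    specs <- lapply(fits, `[[`, "spec")
    cv <- loocv_precomputed(Kw, y, C)
  }
  structure(list(mode = mode, family = family, C = C, specs = specs,
                 weights = weights, svm = svm, blocks = blocks,
                 train_ids = rownames(fm_values(fm)), labels = y,
                 loocv = cv),
            class = "msmg_classifier")
}

family_spec <- function(family, sigma = NULL) {
  switch(family,
         linear = kernel_spec("linear"),
         poly = kernel_spec("polynomial", degree = 3),
         RBF = kernel_spec("rbf", sigma = sigma))
}

mode_blocks <- function(fm, mode) {
  stopifnot(inherits(fm, "feature_matrix"))
  expr_cols <- feature_columns(fm, "expression")
  chip_cols <- feature_columns(fm, "chip")
  V <- fm$values
  switch(mode,
    micro = list(expr = V[, expr_cols, drop = FALSE]),
    chip = {
      if (!length(chip_cols)) stop("feature matrix has no ChIP block")
      list(chip = V[, chip_cols, drop = FALSE])
    },
    simple = {
      if (!length(chip_cols) || !length(expr_cols))
        stop("simple mode needs both data types")
      list(expr = V[, expr_cols, drop = FALSE],
           chip = V[, chip_cols, drop = FALSE])
    },
    weight = {
      if (!length(chip_cols) || !length(expr_cols))
        stop("weight mode needs both data types")
      list(expr = V[, expr_cols, drop = FALSE],
           chip = V[, chip_cols, drop = FALSE])
    })
}

# select sigma (flat LOOCV) if needed, train on the full block, return
# model + Gram + training LOOCV result
fit_block <- function(X, y, spec, C, grid) {
  if (spec$family == "rbf" && is.null(spec$sigma)) {
    cv <- loocv_svm(X, y, spec, C = C, selection = "flat", grid = grid)
    spec$sigma <- cv$sigma
  } else {
    cv <- NULL
  }
  K <- compute_kernel(X, spec = spec)
  if (is.null(cv)) cv <- loocv_precomputed(K, y, C)
  list(model = train_svm(K, y, C = C, check_psd = FALSE), K = K,
       spec = spec, cv = cv)
}

loocv_precomputed <- function(K, y, C) {
  scores <- loocv_scores_kernel(K, y, C)
  cc <- confusion_counts(scores > 0, y > 0)
  structure(list(confusion = cc, metrics = confusion_metrics(cc),
                 scores = setNames(scores, rownames(K)),
                 predicted = scores > 0, sigma = NULL,
                 selection = "none", n_folds = length(y), C = C),
            class = "loocv_result")
}

#' Score new genes with a trained pipeline
#'
#' @param object An `msmg_classifier`.
#' @param fm_new A `feature_matrix` built with the same parameters as
#'   the training one (matching feature names), or a plain matrix with
#'   matching columns.
#' @param ... Unused.
#' @return Data frame with `gene_id`, `score`, `label`.
#' @export
predict.msmg_classifier <- function(object, fm_new, ...) {
  V <- fm_values(fm_new)
  cross <- function(block_name, spec) {
    Xtr <- object$blocks[[block_name]]
    cols <- colnames(Xtr)
    if (!all(cols %in% colnames(V)))
      stop("new features lack the training columns of block ", block_name)
    compute_kernel(V[, cols, drop = FALSE], Xtr, spec)
  }
  Kt <- if (object$mode == "weight") {
    weighted_kernel(cross("expr", object$specs[[1]]),
                    cross("chip", object$specs[[2]]),
                    object$weights[1], object$weights[2])
  } else {
    Xtr <- do.call(cbind, object$blocks)
    cols <- colnames(Xtr)
    if (!all(cols %in% colnames(V)))
      stop("new features lack the training columns")
    compute_kernel(V[, cols, drop = FALSE], Xtr, object$specs[[1]])
  }
  colnames(Kt) <- object$svm$gene_ids
  predict(object$svm, Kt)
}

#' LOOCV evaluation of one data-type/kernel configuration
#'
#' @inheritParams msmg_train
#' @param selection Sigma-selection protocol for RBF, see
#'   [loocv_svm()]; the weight mode always fixes its per-type sigmas
#'   and weights on the full training set first.
#' @return A `loocv_result`.
#' @export
loocv_mode <- function(fm, labels, mode = "simple", family = "RBF", C = 1,
                       selection = "flat", grid = sigma_grid(n_points = 7)) {
  y <- to_pm1(labels)
  blocks <- mode_blocks(fm, mode)
  if (mode != "weight") {
    X <- do.call(cbind, blocks)
    loocv_svm(X, y, family_spec(family), C = C, selection = selection,
              grid = grid)
  } else {
    fits <- lapply(blocks, fit_block, y = y, spec = family_spec(family),
                   C = C, grid = grid)
    w <- vapply(fits, function(f) {
      f1 <- f$cv$metrics$F1
      if (is.na(f1)) 0 else f1
    }, numeric(1))
    Kw <- weighted_kernel(fits[[1]]$K, fits[[2]]$K, w[1], w[2])
    res <- loocv_precomputed(Kw, y, C)
    res$weights <- w
    res$sigma <- lapply(fits, function(f) f$spec$sigma)
    res
  }
}

#' Run the full data-type x kernel experiment grid
#'
#' Evaluates every combination of the seven data-type strategies
#' (`micro`, `chip_binary`, `chip_contin`, `weight_binary`,
#' `weight_contin`, `simple_binary`, `simple_contin`) and three kernel
#' families (`linear`, `poly`, `RBF`) by LOOCV, producing one row per
#' configuration labeled `mode_kernel` (e.g. `weight_contin_RBF`).
#'
#' @param fm_binary Combined `feature_matrix` with the binary ChIP
#'   block.
#' @param fm_contin Combined `feature_matrix` with the continuous ChIP
#'   block.
#' @param labels Training labels.
#' @param modes,kernels Subsets of the grid to run.
#' @param C,selection,grid Passed to [loocv_mode()].
#' @return Data frame with columns `config`, `TP`, `FP`, `TN`, `FN`,
#'   `TPR`, `FPR`, `accuracy`, plus an attribute `details` logging the
#'   selected hyperparameters.
#' @export
run_experiment_grid <- function(fm_binary, fm_contin, labels,
                                modes = c("micro", "chip_binary",
                                          "chip_contin", "weight_binary",
                                          "weight_contin", "simple_binary",
                                          "simple_contin"),
                                kernels = c("linear", "poly", "RBF"),
                                C = 1, selection = "flat",
                                grid = sigma_grid(n_points = 7)) {
  known_modes <- c("micro", "chip_binary", "chip_contin", "weight_binary",
                   "weight_contin", "simple_binary", "simple_contin")
  if (!all(modes %in% known_modes))
    stop("usage error: unknown mode(s): ",
         paste(setdiff(modes, known_modes), collapse = ", "))
  if (!all(kernels %in% c("linear", "poly", "RBF")))
    stop("usage error: unknown kernel(s)")
  rows <- list()
  details <- list()
  for (mode in modes) {
    fm <- if (grepl("binary", mode)) fm_binary else fm_contin
    base_mode <- sub("_(binary|contin)$", "", mode)
    if (base_mode == "micro") fm <- fm_contin %||% fm_binary
    for (kern in kernels) {
      res <- loocv_mode(fm, labels, mode = base_mode, family = kern,
                        C = C, selection = selection, grid = grid)
      cc <- res$confusion
      mt <- res$metrics
      config <- paste0(mode, "_", kern)
      rows[[config]] <- data.frame(
        config = config, TP = cc$TP, FP = cc$FP, TN = cc$TN, FN = cc$FN,
        TPR = mt$TPR, FPR = mt$FPR, accuracy = mt$accuracy,
        stringsAsFactors = FALSE)
      details[[config]] <- list(sigma = res$sigma, C = C,
                                weights = res$weights)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "details") <- details
  out
}

#' Serialize / restore a trained pipeline
#'
#' Writes the full `msmg_classifier` — dual solution, kernel specs,
#' data-type weights and the stored training feature blocks — to one
#' JSON file, so unseen genes can be scored later without retraining.
#'
#' @param model An `msmg_classifier`.
#' @param path JSON file path.
#' @param extra Optional named list stored verbatim (e.g. feature-build
#'   parameters).
#' @return `save_msmg_model` the path invisibly; `load_msmg_model` the
#'   restored classifier.
#' @export
save_msmg_model <- function(model, path, extra = NULL) {
  stopifnot(inherits(model, "msmg_classifier"))
  enc_mat <- function(m) list(values = unname(m), rows = rownames(m),
                              cols = colnames(m))
  obj <- list(mode = model$mode, family = model$family, C = model$C,
              specs = lapply(model$specs, unclass),
              weights = model$weights,
              svm = unclass(model$svm),
              blocks = lapply(model$blocks, enc_mat),
              train_ids = model$train_ids, labels = model$labels,
              extra = extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_msmg_model
#' @export
load_msmg_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  dec_mat <- function(e) {
    m <- e$values
    dimnames(m) <- list(e$rows, e$cols)
    m
  }
  blocks <- lapply(obj$blocks, dec_mat)
  svm <- obj$svm
  svm$y <- as.numeric(svm$y)
  class(svm) <- "svm_model"
  specs <- lapply(obj$specs, function(s) {
    s <- as.list(s)
    structure(list(family = s$family, degree = s$degree,
                   sigma = s$sigma), class = "kernel_spec")
  })
  structure(list(mode = obj$mode, family = obj$family, C = obj$C,
                 specs = specs, weights = obj$weights, svm = svm,
                 blocks = blocks, train_ids = obj$train_ids,
                 labels = as.numeric(obj$labels), extra = obj$extra),
            class = "msmg_classifier")
}

#' Parse and validate a labeled training gene list
#'
#' Accepts either one two-column TSV (`gene_id`, `label` with values
#' positive/negative) or two plain-text files of ids.  Duplicated or
#' cross-listed genes are rejected by name.
#'
#' @param path TSV path, or the positive-list path when `negatives` is
#'   given.
#' @param negatives Optional path of the negative-list file.
#' @return Data frame with `gene_id` and `label`.
#' @export
validate_training_list <- function(path, negatives = NULL) {
  if (is.null(negatives)) {
    if (file.size(path) == 0) stop("empty training list: ", path)
    d <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
    if (!all(c("gene_id", "label") %in% names(d)))
      stop("training list needs gene_id and label columns")
  } else {
    pos <- read_gene_list(path)
    neg <- read_gene_list(negatives)
    if (!length(pos) || !length(neg)) stop("empty training list")
    d <- data.frame(gene_id = c(pos, neg),
                    label = rep(c("positive", "negative"),
                                c(length(pos), length(neg))),
                    stringsAsFactors = FALSE)
  }
  if (nrow(d) == 0) stop("empty training list")
  dup <- unique(d$gene_id[duplicated(d$gene_id)])
  if (length(dup)) {
    both <- dup[vapply(dup, function(g)
      length(unique(d$label[d$gene_id == g])) > 1, logical(1))]
    if (length(both))
      stop("gene(s) listed in both classes: ", paste(both, collapse = ", "))
    stop("duplicated gene(s): ", paste(dup, collapse = ", "))
  }
  if (!all(d$label %in% c("positive", "negative")))
    stop("labels must be positive/negative")
  d
}

#' The packaged expert-curated training gene list
#'
#' 46 genes labeled positive (MSMG, e.g. Nanog, Pou5f1, Sox2, Esrrb)
#' and 70 labeled negative (lineage and differentiation regulators),
#' shipped as a plain-text fixture so the real training labels are
#' usable without downloads.
#'
#' @return Data frame with `gene_id` and `label` (116 rows).
#' @export
training_gene_set <- function() {
  validate_training_list(system.file("extdata", "training_genes.tsv",
                                     package = "stemsvm", mustWork = TRUE))
}

#' Published evaluation tables shipped as reference inputs
#'
#' `published_svm_performance()` returns the printed LOOCV confusion
#' counts and metrics of the 21 data-type/kernel configurations on the
#' real study features; `published_signal_to_noise()` the corresponding
#' printed signal-to-noise ratios; `published_fold_change_accuracy()`
#' the two printed accuracies of the ES/EB fold-change baseline.  These
#' are inputs for worked-example arithmetic — the package does not
#' recompute them from raw data.
#'
#' @return A data frame (or numeric vector for the fold-change
#'   accuracies).
#' @export
published_svm_performance <- function() {
  read.table(system.file("extdata", "published_svm_performance.tsv",
                         package = "stemsvm", mustWork = TRUE),
             sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' @rdname published_svm_performance
#' @export
published_signal_to_noise <- function() {
  read.table(system.file("extdata", "published_signal_to_noise.tsv",
                         package = "stemsvm", mustWork = TRUE),
             sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' @rdname published_svm_performance
#' @export
published_fold_change_accuracy <- function() {
  d <- read.table(system.file("extdata", "published_fold_change_accuracy.tsv",
                              package = "stemsvm", mustWork = TRUE),
                  sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  setNames(d$accuracy, d$dataset)
}
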