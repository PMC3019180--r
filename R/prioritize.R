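#' Signal-to-noise prioritization of candidate gene lists
#'
#' Applies a trained classifier to two candidate lists — one expected
#' to be enriched for true positives (e.g. hits of a self-renewal RNAi
#' screen) and one expected irrelevant — and reports the percentage of
#' predicted MSMGs in each plus their ratio,
#' \deqn{ratio = \%\,predicted\ MSMG\ (positive\ list) /
#'       \%\,predicted\ MSMG\ (negative\ list),}
#' interpretable as a signal-to-noise ratio of the screen.
#'
#' @param model An `msmg_classifier` (or any object with a compatible
#'   `predict` method returning `gene_id`/`label`).
#' @param positive_candidates,negative_candidates Character vectors of
#'   gene ids; must be present in `fm` and should be disjoint from the
#'   training genes (a warning is raised otherwise — the point of the
#'   test is genes the classifier has never seen).
#' @param fm `feature_matrix` covering the candidate genes.
#' @return Object of class `prioritization_result`: `fraction_positive`
#'   and `fraction_negative` (percentages in \[0, 100\]), `ratio`
#'   (`Inf` with `infinite = TRUE` when no negative-list gene is
#'   predicted MSMG), and the per-gene `predictions`.
#' @export
signal_to_noise <- function(model, positive_candidates, negative_candidates,
                            fm) {
  ids <- c(positive_candidates, negative_candidates)
  V <- fm_values(fm)
  missing <- setdiff(ids, rownames(V))
  if (length(missing))
    stop("candidate genes absent from the feature matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  if (!is.null(model$train_ids)) {
    seen <- intersect(ids, model$train_ids)
    if (length(seen))
      warning("candidate list overlaps the training set: ",
              paste(utils::head(seen, 5), collapse = ", "))
  }
  sub <- fm_row_subset(fm, ids)
  pred <- predict(model, sub)
  pred$list <- rep(c("positive", "negative"),
                   c(length(positive_candidates),
                     length(negative_candidates)))
  frac <- function(lst)
    100 * mean(pred$label[pred$list == lst] == "MSMG")
  fp <- frac("positive")
  fn <- frac("negative")
  inf <- fn == 0
  structure(list(fraction_positive = fp, fraction_negative = fn,
                 ratio = if (inf) Inf else fp / fn, infinite = inf,
                 predictions = pred),
            class = "prioritization_result")
}

fm_row_subset <- function(fm, ids) {
  if (inherits(fm, "feature_matrix")) {
    fm$values <- fm$values[ids, , drop = FALSE]
    fm$gene_ids <- ids
    fm
  } else {
    fm[ids, , drop = FALSE]
  }
}

#' @export
print.prioritization_result <- function(x, ...) {
  cat(sprintf("predicted MSMG: %.1f%% of positive list, %.1f%% of negative list\n",
              x$fraction_positive, x$fraction_negative))
  cat(sprintf("signal-to-noise ratio: %s\n",
              if (x$infinite) "infinite (no negative-list predictions)"
              else sprintf("%.2f", x$ratio)))
  invisible(x)
}

#' Genes consistently predicted MSMG across configurations
#'
#' Intersects per-configuration predictions to find candidates that
#' come out MSMG no matter which data type or kernel is used — the
#' persistent "false positives" that are plausible unrecognized true
#' positives.
#'
#' @param predictions List (length >= 2) of prediction data frames with
#'   `gene_id` and `label`, all over the same gene universe.
#' @return Character vector of gene ids predicted `"MSMG"` in every
#'   configuration (possibly empty).
#' @export
consistent_misclassified <- function(predictions) {
  if (length(predictions) < 2L)
    stop("need at least 2 configurations")
  universes <- lapply(predictions, function(p) sort(p$gene_id))
  if (!all(vapply(universes[-1], identical, logical(1), universes[[1]])))
    stop("inconsistent gene universes across configurations")
  hit_sets <- lapply(predictions, function(p) p$gene_id[p$label == "MSMG"])
  Reduce(intersect, hit_sets)
}

#' Two-sample t-test on per-configuration prediction percentages
#'
#' Compares the predicted-MSMG percentages of the positive lists
#' against those of the negative lists across configurations.  Welch
#' (unequal variance) by default, pooled optionally.  Degenerate input
#' with zero variance in both groups and equal means returns t = 0,
#' p = 1 instead of failing.
#'
#' @param pos_fractions,neg_fractions Numeric vectors (>= 2 values
#'   each).
#' @param pooled Use the pooled-variance statistic (default `FALSE`).
#' @return List with `statistic`, `df`, `p_value`, `method`.
#' @export
compare_ratio_groups <- function(pos_fractions, neg_fractions,
                                 pooled = FALSE) {
  x <- pos_fractions; y <- neg_fractions
  if (length(x) < 2L || length(y) < 2L)
    stop("need at least 2 values per group")
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y))
      return(list(statistic = 0, df = nx + ny - 2, p_value = 1,
                  method = if (pooled) "pooled" else "welch"))
    stop("zero variance in both groups with unequal means")
  }
  if (pooled) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  t <- (mean(x) - mean(y)) / se
  list(statistic = t, df = df, p_value = 2 * pt(-abs(t), df),
       method = if (pooled) "pooled" else "welch")
}
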