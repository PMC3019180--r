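#' Expression feature layout of the training compendium
#'
#' The expression side of the feature space consists of 79 named
#' conditions drawn from four microarray studies of mouse ES cells:
#' mean expression in undifferentiated ES cells and in embryoid bodies
#' (2 features), two 11-point undirected differentiation time courses
#' (V6.5 and R1 lines, 22 features), a 7-point retinoic-acid-induced
#' differentiation course (7 features), and 8-point time courses for
#' six pluripotency-factor shRNA knockdown lines (Esrrb, Nanog, Oct4,
#' Sox2, Tbx3, Tcl1; 48 features).
#'
#' @return A data frame with one row per expression feature and columns
#'   `name` (unique feature label), `dataset` (study tag), `condition`
#'   and `time` (time-point index within its course, `NA` for the two
#'   mean features).  Always 79 rows.
#' @examples
#' nrow(study_layout())  # 79
#' @export
study_layout <- function() {
  kd_lines <- c("Esrrb", "Nanog", "Oct4", "Sox2", "Tbx3", "Tcl1")
  rows <- list(
    data.frame(name = c("ES_mean", "EB_mean"),
               dataset = "eseb", condition = c("ES", "EB"), time = NA_integer_),
    data.frame(name = sprintf("diffV65_t%02d", 1:11),
               dataset = "diffV65", condition = "differentiation", time = 1:11),
    data.frame(name = sprintf("diffR1_t%02d", 1:11),
               dataset = "diffR1", condition = "differentiation", time = 1:11),
    data.frame(name = sprintf("RA_t%d", 1:7),
               dataset = "RA", condition = "RA_differentiation", time = 1:7),
    do.call(rbind, lapply(kd_lines, function(tf)
      data.frame(name = sprintf("kd%s_t%d", tf, 1:8),
                 dataset = "knockdown", condition = paste0(tf, "_shRNA"),
                 time = 1:8)))
  )
  layout <- do.call(rbind, rows)
  rownames(layout) <- NULL
  stopifnot(nrow(layout) == 79L, !anyDuplicated(layout$name))
  layout
}

#' Default transcription-factor panel for the ChIP-seq features
#'
#' Twelve factors profiled genome-wide in mouse ES cells; identities are
#' opaque labels as far as the classifier is concerned.
#'
#' @return Character vector of length 12.
#' @export
chip_tf_names <- function() {
  c("Nanog", "Oct4", "Sox2", "Smad1", "E2f1", "Tcfcp2l1",
    "Zfx", "Stat3", "Klf4", "Esrrb", "Nmyc", "Cmyc")
}

# per-feature class-effect weights used by the expression simulator:
# positives are high in ES, decay along differentiation/RA courses and
# are progressively depleted under pluripotency-factor knockdown
layout_effect_profile <- function(layout) {
  w <- numeric(nrow(layout))
  for (i in seq_len(nrow(layout))) {
    d <- layout$dataset[i]
    t <- layout$time[i]
    w[i] <- switch(d,
      eseb = if (layout$condition[i] == "ES") 1 else 0,
      diffV65 = ,
      diffR1 = (11 - t) / 10,
      RA = (7 - t) / 6,
      knockdown = -(t - 1) / 7,
      0)
  }
  w
}
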