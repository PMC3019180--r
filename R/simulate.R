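#' Configuration for the synthetic study generator
#'
#' Collects and validates every knob of the synthetic-data module.  The
#' defaults restate the structure of the training compendium: 46
#' positive (MSMG) and 70 negative training genes, 12 TF ChIP-seq peak
#' sets with class-dependent binding near the TSS, and unlabeled
#' candidate pools from which RNAi-screen-like test lists are drawn.
#'
#' @param n_pos,n_neg Number of positive / negative training genes
#'   (each at least 2; defaults 46 / 70).
#' @param n_unlabeled Number of unlabeled genes; half carry a latent
#'   positive-like signal, half are background (default 300).
#' @param effect_size Dimensionless multiplier on the class-dependent
#'   log2 expression differences (default 2).
#' @param noise_sd Log2-scale s.d. of the multiplicative expression
#'   noise (default 0.5).
#' @param p_peak_pos,p_peak_neg Per-TF probability that a positive
#'   (resp. negative) gene receives a binding peak (defaults 0.8 / 0.2).
#' @param peak_distance_scale Laplace scale (bp) of the peak-center
#'   offset from the TSS (default 5000).
#' @param intensity_log_mean,intensity_log_sd Log-normal parameters of
#'   peak intensities (defaults 2 and 0.5, natural-log scale).
#' @param chrom_length Length (bp) of the single synthetic chromosome
#'   (default 1e8).
#' @param n_candidates_pos,n_candidates_neg Sizes of the generated
#'   positive / negative candidate test lists (defaults 126 / 101, the
#'   ID-matched sizes of the two screens the framework was applied to).
#' @param enrichment Fraction of the positive candidate list drawn from
#'   the latent signal population (default 0.8).
#' @param seed Integer seed; every generator output is a deterministic
#'   function of the configuration.
#' @return An object of class `sim_config` (a validated list).
#' @export
simulation_config <- function(n_pos = 46, n_neg = 70, n_unlabeled = 300,
                              effect_size = 2, noise_sd = 0.5,
                              p_peak_pos = 0.8, p_peak_neg = 0.2,
                              peak_distance_scale = 5000,
                              intensity_log_mean = 2, intensity_log_sd = 0.5,
                              chrom_length = 1e8,
                              n_candidates_pos = 126, n_candidates_neg = 101,
                              enrichment = 0.8, seed = 1L) {
  cfg <- list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
              n_unlabeled = as.integer(n_unlabeled),
              effect_size = effect_size, noise_sd = noise_sd,
              p_peak_pos = p_peak_pos, p_peak_neg = p_peak_neg,
              peak_distance_scale = peak_distance_scale,
              intensity_log_mean = intensity_log_mean,
              intensity_log_sd = intensity_log_sd,
              chrom_length = chrom_length,
              n_candidates_pos = as.integer(n_candidates_pos),
              n_candidates_neg = as.integer(n_candidates_neg),
              enrichment = enrichment, seed = as.integer(seed))
  if (cfg$n_pos < 2L || cfg$n_neg < 2L)
    stop("configuration error: n_pos and n_neg must both be >= 2")
  if (cfg$n_unlabeled < 0L)
    stop("configuration error: n_unlabeled must be >= 0")
  if (cfg$noise_sd < 0)
    stop("configuration error: noise_sd must be >= 0")
  for (p in c("p_peak_pos", "p_peak_neg", "enrichment"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1)
      stop("configuration error: ", p, " must lie in [0, 1]")
  if (cfg$peak_distance_scale <= 0 || cfg$chrom_length <= 0)
    stop("configuration error: scales must be positive")
  class(cfg) <- "sim_config"
  cfg
}

rlaplace <- function(n, scale) {
  u <- runif(n) - 0.5
  -scale * sign(u) * log1p(-2 * abs(u))
}

#' Generate the labeled gene universe
#'
#' Draws gene annotations on a single synthetic chromosome: unique ids,
#' collision-free TSS coordinates, random strand, and class labels.
#' Unlabeled genes additionally carry a hidden `latent` class (half
#' signal-like, half background) that drives their simulated expression
#' and binding and later the candidate-list construction.
#'
#' @param config A [simulation_config()].
#' @return Data frame with columns `gene_id`, `chrom`, `tss`, `strand`,
#'   `label` (positive/negative/unlabeled) and `latent`.
#' @export
generate_universe <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_pos + config$n_neg + config$n_unlabeled
  tss <- sample.int(config$chrom_length - 1L, n, replace = FALSE)
  label <- c(rep("positive", config$n_pos), rep("negative", config$n_neg),
             rep("unlabeled", config$n_unlabeled))
  n_sig <- config$n_unlabeled %/% 2L
  latent <- c(rep("positive", config$n_pos), rep("negative", config$n_neg),
              rep("positive", n_sig),
              rep("negative", config$n_unlabeled - n_sig))
  data.frame(gene_id = sprintf("G%04d", seq_len(n)),
             chrom = "chrS", tss = tss,
             strand = sample(c("+", "-"), n, replace = TRUE),
             label = label, latent = latent,
             stringsAsFactors = FALSE)
}

#' Simulate raw expression over the 79-condition layout
#'
#' Latent-positive genes get expression elevated in the ES condition,
#' decaying to baseline along the differentiation and RA courses, and
#' progressively depleted along the knockdown courses; latent-negative
#' genes are flat.  The class effect (in log2 units) is
#' `effect_size * w(condition)` with the profile `w` in \[-1, 1\];
#' log-normal multiplicative noise of log2-scale s.d. `noise_sd` is
#' added, and per-gene baselines are N(7, 1) on the log2 scale.
#'
#' @param genes Universe from [generate_universe()].
#' @param layout The [study_layout()] (must have 79 rows).
#' @param config A [simulation_config()].
#' @return Strictly positive numeric matrix, genes x 79, with gene ids
#'   as row names and layout names as column names.
#' @export
simulate_expression <- function(genes, layout = study_layout(), config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(layout) != 79L)
    stop("layout error: expected 79 expression descriptors, got ", nrow(layout))
  set.seed(config$seed + 1L)
  n <- nrow(genes)
  w <- layout_effect_profile(layout)
  baseline <- rnorm(n, mean = 7, sd = 1)
  cls <- as.numeric(genes$latent == "positive")
  log2e <- outer(baseline, rep(1, 79)) +
    config$effect_size * outer(cls, w) +
    matrix(rnorm(n * 79, sd = config$noise_sd), n, 79)
  E <- 2^log2e
  dimnames(E) <- list(genes$gene_id, layout$name)
  E
}

#' Simulate TF ChIP-seq peak sets
#'
#' For each transcription factor, each gene receives a peak with
#' class-dependent probability (`p_peak_pos` for latent positives,
#' `p_peak_neg` otherwise).  Peak centers are offset from the TSS by a
#' Laplace deviate of scale `peak_distance_scale` — giving the
#' exponential-tail distance spectrum the distance-decay binding score
#' operates on — and intensities are log-normal.  Peaks are 200 bp wide,
#' clipped to the chromosome.
#'
#' @param genes Universe from [generate_universe()].
#' @param config A [simulation_config()].
#' @param n_tfs Number of factors (default 12).
#' @param tf_names Factor labels (default [chip_tf_names()]).
#' @return Named list of `n_tfs` data frames with columns `chrom`,
#'   `start`, `end`, `tf`, `intensity` plus a provenance column
#'   `gene_id` naming the gene each peak was planted for (dropped when
#'   written to disk).
#' @export
simulate_chip_peaks <- function(genes, config, n_tfs = 12,
                                tf_names = chip_tf_names()) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(genes) == 0L) stop("genes must be non-empty")
  if (config$p_peak_pos < config$p_peak_neg)
    warning("inverted signal: p_peak_pos < p_peak_neg")
  tf_names <- rep_len(tf_names, n_tfs)
  set.seed(config$seed + 2L)
  n <- nrow(genes)
  p <- ifelse(genes$latent == "positive", config$p_peak_pos, config$p_peak_neg)
  out <- vector("list", n_tfs)
  for (j in seq_len(n_tfs)) {
    bound <- runif(n) < p
    nb <- sum(bound)
    centers <- round(genes$tss[bound] +
                       rlaplace(nb, config$peak_distance_scale))
    centers <- pmin(pmax(centers, 100), config$chrom_length - 100)
    out[[j]] <- data.frame(
      chrom = "chrS",
      start = as.integer(centers - 100),
      end = as.integer(centers + 100),
      tf = tf_names[j],
      intensity = rlnorm(nb, config$intensity_log_mean,
                         config$intensity_log_sd),
      gene_id = genes$gene_id[bound],
      stringsAsFactors = FALSE)
  }
  names(out) <- tf_names
  out
}

#' Draw candidate test lists with planted enrichment
#'
#' Emulates the two RNAi-screen test sets: the positive list samples a
#' configurable fraction (`enrichment`) of its genes from the latent
#' signal population of the unlabeled pool, the rest — and the whole
#' negative list — from the independent background population.  The two
#' lists are disjoint from each other and from the training genes.
#'
#' @param genes Universe from [generate_universe()].
#' @param config A [simulation_config()].
#' @return List with character vectors `positive` and `negative`.
#' @export
simulate_candidate_lists <- function(genes, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  unl <- genes[genes$label == "unlabeled", ]
  sig <- unl$gene_id[unl$latent == "positive"]
  bkg <- unl$gene_id[unl$latent == "negative"]
  n_sig <- round(config$enrichment * config$n_candidates_pos)
  n_fill <- config$n_candidates_pos - n_sig
  if (n_sig > length(sig) || n_fill + config$n_candidates_neg > length(bkg))
    stop("configuration error: unlabeled pool too small for candidate lists")
  pos <- c(sample(sig, n_sig), sample(bkg, n_fill))
  neg <- sample(setdiff(bkg, pos), config$n_candidates_neg)
  list(positive = sort(pos), negative = sort(neg))
}

#' Run the whole generator in one call
#'
#' @param config A [simulation_config()].
#' @return List with elements `genes`, `layout`, `expression`, `peaks`,
#'   `candidates` and the `config` itself.
#' @examples
#' sim <- simulate_study(simulation_config(n_unlabeled = 0, seed = 1))
#' dim(sim$expression)  # 116 x 79
#' @export
simulate_study <- function(config = simulation_config()) {
  genes <- generate_universe(config)
  layout <- study_layout()
  expr <- simulate_expression(genes, layout, config)
  peaks <- simulate_chip_peaks(genes, config)
  cand <- if (config$n_unlabeled >= config$n_candidates_pos +
                config$n_candidates_neg)
    simulate_candidate_lists(genes, config) else NULL
  list(genes = genes, layout = layout, expression = expr, peaks = peaks,
       candidates = cand, config = config)
}
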