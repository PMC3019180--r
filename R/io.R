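#' Write a simulated study to plain-text fixtures
#'
#' Serializes a gene universe, expression matrix, peak sets and label
#' lists in the formats the pipeline consumes: genes as 6-column BED
#' (0-based half-open, TSS as the interval start), expression as TSV
#' with a `gene_id` column plus the 79 named features, one 5-column
#' BED-like file per TF (`chrom start end tf_name intensity`), and
#' plain-text gene lists (one id per line).
#'
#' @param genes,expression,peaks Components as produced by
#'   [simulate_study()]; gene sets must be consistent.
#' @param out_dir Output directory (created if needed).
#' @param candidates Optional list with `positive`/`negative` id
#'   vectors.
#' @return Named character vector of written paths, invisibly.
#' @export
write_fixtures <- function(genes, expression, peaks, out_dir,
                           candidates = NULL) {
  if (!identical(genes$gene_id, rownames(expression)))
    stop("gene sets of annotation and expression matrix differ")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("I/O error: cannot create ", out_dir)
  paths <- c(genes = file.path(out_dir, "genes.bed"),
             expression = file.path(out_dir, "expression.tsv"))

  bed <- data.frame(genes$chrom, genes$tss, genes$tss + 1L, genes$gene_id,
                    0L, genes$strand)
  write.table(bed, paths["genes"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)

  expr <- data.frame(gene_id = rownames(expression), expression,
                     check.names = FALSE)
  write.table(expr, paths["expression"], sep = "\t", quote = FALSE,
              row.names = FALSE)

  for (tf in names(peaks)) {
    p <- file.path(out_dir, sprintf("peaks_%s.bed", tf))
    write.table(peaks[[tf]][, c("chrom", "start", "end", "tf", "intensity")],
                p, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    paths[paste0("peaks_", tf)] <- p
  }

  for (lab in c("positive", "negative", "unlabeled")) {
    ids <- genes$gene_id[genes$label == lab]
    if (length(ids)) {
      p <- file.path(out_dir, sprintf("genes_%s.txt", lab))
      writeLines(ids, p)
      paths[paste0("list_", lab)] <- p
    }
  }
  if (!is.null(candidates)) {
    for (lab in names(candidates)) {
      p <- file.path(out_dir, sprintf("candidates_%s.txt", lab))
      writeLines(candidates[[lab]], p)
      paths[paste0("candidates_", lab)] <- p
    }
  }
  invisible(paths)
}

#' Read gene annotation from a BED file
#'
#' @param path 6-column BED (chrom, start, end, name, score, strand);
#'   the interval start is taken as the TSS.
#' @return Data frame with `gene_id`, `chrom`, `tss`, `strand`.
#' @export
read_gene_bed <- function(path) {
  b <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  data.frame(gene_id = b[[4]], chrom = b[[1]], tss = b[[2]],
             strand = b[[6]], stringsAsFactors = FALSE)
}

#' Read an expression TSV written by [write_fixtures()]
#' @param path TSV with a `gene_id` column and one column per feature.
#' @return Numeric matrix with gene ids as row names.
#' @export
read_expression_tsv <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                  stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$gene_id
  m
}

#' Read peak files (5-column BED-like) into a named list
#' @param paths Character vector of file paths; names default to the
#'   TF name in column 4 of each file.
#' @return Named list of peak data frames.
#' @export
read_peak_beds <- function(paths) {
  out <- lapply(paths, function(p) {
    b <- read.table(p, sep = "\t", stringsAsFactors = FALSE)
    names(b) <- c("chrom", "start", "end", "tf", "intensity")
    b
  })
  names(out) <- vapply(out, function(b) b$tf[1], "")
  out
}

#' Read a plain-text gene list (one id per line)
#' @param path File path.
#' @return Character vector.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x[nzchar(x)]
}

#' Read a simulation configuration from YAML
#'
#' The YAML keys mirror the arguments of [simulation_config()];
#' unknown keys are rejected.
#'
#' @param path YAML file.
#' @return A `sim_config` object.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(simulation_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  do.call(simulation_config, vals)
}

#' Write a simulation configuration to YAML
#' @param config A `sim_config`.
#' @param path Output file.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# provenance header used on grid/result tables: a small polynomial
# hash of the run configuration plus seed and package version
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

write_result_table <- function(df, path, config = NULL, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# stemsvm %s seed=%s config=%s",
                     as.character(packageVersion("stemsvm")),
                     as.character(seed), config_hash(config)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
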