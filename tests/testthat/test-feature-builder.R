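test_that("normalize_expression implements the unit-norm log scaling", {
  X <- normalize_expression(rep(2, 79))
  expect_equal(X, rep(1 / sqrt(79), 79))
  expect_equal(normalize_expression(c(2, 4, 16)),
               c(1, 2, 4) / sqrt(21))
  expect_equal(normalize_expression(c(1, 2, 2))[1], 0)  # log2(1) = 0
  expect_error(normalize_expression(c(1, 0, 2)), "positive")
  expect_error(normalize_expression(c(-1, 2)), "positive")
  expect_error(normalize_expression(rep(1, 5)), "degenerate")
  # pseudocount option admits zeros
  expect_silent(normalize_expression(c(0, 1, 3), pseudocount = 1))
})

test_that("scaled expression vectors have unit norm (property)", {
  set.seed(42)
  for (i in 1:25) {
    E <- 2^rnorm(79, mean = 7, sd = 2)
    expect_equal(sum(normalize_expression(E)^2), 1, tolerance = 1e-9)
  }
})

test_that("binary_binding applies the inclusive TSS window", {
  gene <- data.frame(chrom = "chrS", tss = 10000)
  pk <- function(center) data.frame(chrom = "chrS", start = center - 100,
                                    end = center + 100, intensity = 1)
  expect_equal(binary_binding(pk(10500), gene, window = 1000), 1L)
  expect_equal(binary_binding(pk(11000), gene, window = 1000), 1L)  # boundary
  expect_equal(binary_binding(pk(11001), gene, window = 1000), 0L)
  expect_equal(binary_binding(pk(10500)[0, ], gene, window = 1000), 0L)
  expect_equal(binary_binding(data.frame(chrom = "chr2", start = 9900,
                                         end = 10100, intensity = 1),
                              gene, window = 1000), 0L)
  expect_error(binary_binding(pk(1), gene, window = 0), "positive")
})

test_that("continuous_binding is the distance-decayed intensity sum", {
  gene <- data.frame(chrom = "chrS", tss = 50000)
  mk <- function(centers, g) data.frame(chrom = "chrS",
                                        start = centers - 100,
                                        end = centers + 100, intensity = g)
  expect_equal(continuous_binding(mk(1, 1)[0, ], gene), 0)
  expect_equal(continuous_binding(mk(50000, 5), gene), 5)
  d0 <- 5000
  expect_equal(continuous_binding(mk(c(50000, 50000 + d0), c(2, 3)),
                                  gene, d0 = d0),
               2 + 3 * exp(-1))
  expect_error(continuous_binding(mk(50000, -2), gene), "non-negative")
})

test_that("binding score is additive, distance-monotone, with the right limits", {
  gene <- data.frame(chrom = "chrS", tss = 1e5)
  mk <- function(centers, g) data.frame(chrom = "chrS", start = centers - 50,
                                        end = centers + 50, intensity = g)
  set.seed(7)
  for (i in 1:10) {
    centers <- 1e5 + sample(-2e4:2e4, 4)
    g <- runif(4, 0.5, 5)
    a_all <- continuous_binding(mk(centers, g), gene)
    a_sum <- sum(vapply(1:4, function(k)
      continuous_binding(mk(centers[k], g[k]), gene), numeric(1)))
    expect_equal(a_all, a_sum)                     # additivity
    k <- sample(4, 1)
    farther <- centers
    farther[k] <- farther[k] + sign(farther[k] - 1e5 + 0.5) * 5000
    expect_lte(continuous_binding(mk(farther, g), gene), a_all)
    # limits: d0 -> Inf recovers the intensity sum; d0 -> 0+ keeps only d=0
    expect_equal(continuous_binding(mk(centers, g), gene, d0 = 1e12),
                 sum(g), tolerance = 1e-6)
    at_tss <- centers == 1e5
    expect_equal(continuous_binding(mk(centers, g), gene, d0 = 1e-9),
                 sum(g[at_tss]))
  }
  # binary/continuous consistency: no peaks anywhere -> both zero
  empty <- mk(1, 1)[0, ]
  expect_equal(binary_binding(empty, gene, window = 1e9), 0L)
  expect_equal(continuous_binding(empty, gene), 0)
})

test_that("quantile normalization matches the brute-force oracle and limma", {
  set.seed(11)
  M <- matrix(rexp(30), 10, 3)
  expect_equal(quantile_normalize(M), brute_qn(M))
  skip_if_not_installed("limma")
  expect_equal(unname(quantile_normalize(M)),
               unname(limma::normalizeQuantiles(M)))
  # with ties
  Mt <- matrix(sample(1:4, 24, replace = TRUE), 8, 3)
  expect_equal(unname(quantile_normalize(Mt)),
               unname(limma::normalizeQuantiles(Mt)))
})

test_that("quantile normalization fixed points and contracts", {
  M <- cbind(a = c(3, 1, 2, 5), b = c(5, 2, 1, 3))  # column permutations
  Q <- quantile_normalize(M)
  expect_equal(sort(Q[, 1]), sort(Q[, 2]))
  expect_equal(Q[, 1], M[, 1])  # already the reference distribution
  Mc <- matrix(2, 4, 3)
  expect_equal(quantile_normalize(Mc), Mc)
  expect_equal(quantile_normalize(Mc, ties = "first"), Mc)
  # "first" ties preserve the reference multiset exactly, even with ties
  set.seed(13)
  Mz <- matrix(c(rep(0, 12), rexp(12)), 8, 3)
  Qz <- quantile_normalize(Mz, ties = "first")
  expect_equal(sort(Qz[, 2]), sort(Qz[, 1]))
  expect_equal(sort(Qz[, 3]), sort(Qz[, 1]))
  expect_error(quantile_normalize(matrix(1, 1, 3)), "2 rows")
  expect_error(transform_binding_matrix(matrix(-1, 3, 2)), "non-negative")
})

test_that("assemble_features yields the contracted column counts", {
  sim <- quick_sim(seed = 12)
  fm79 <- build_feature_matrix(sim$genes, sim$expression, sim$peaks, "micro")
  fm12b <- build_feature_matrix(sim$genes, sim$expression, sim$peaks,
                                "chip_binary")
  fm12c <- build_feature_matrix(sim$genes, sim$expression, sim$peaks,
                                "chip_contin")
  fm91 <- build_feature_matrix(sim$genes, sim$expression, sim$peaks,
                               "combined_contin")
  expect_equal(ncol(fm79$values), 79)
  expect_equal(ncol(fm12b$values), 12)
  expect_equal(ncol(fm12c$values), 12)
  expect_equal(ncol(fm91$values), 91)
  expect_true(all(fm12b$values %in% 0:1))
  expect_equal(table(fm91$feature_info$source),
               table(factor(rep(c("chip", "expression"), c(12, 79)))),
               ignore_attr = TRUE)
  # QN contract on the continuous chip block: shared sorted values
  chip <- fm91$values[, fm91$feature_info$source == "chip"]
  for (j in 2:12)
    expect_equal(unname(sort(chip[, 1])), unname(sort(chip[, j])))

  other <- fm79$values
  rownames(other) <- rev(rownames(other))
  expect_error(assemble_features(other, fm12b$values, "combined_binary"),
               "alignment")
})
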