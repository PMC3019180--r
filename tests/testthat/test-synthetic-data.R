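test_that("generate_universe produces the requested class structure", {
  cfg <- simulation_config(n_pos = 46, n_neg = 70, n_unlabeled = 0, seed = 1)
  g <- generate_universe(cfg)
  expect_equal(nrow(g), 116)
  expect_equal(sum(g$label == "positive"), 46)
  expect_equal(sum(g$label == "negative"), 70)
  expect_false(anyDuplicated(g$gene_id) > 0)
  expect_false(anyDuplicated(g$tss) > 0)
  expect_true(all(g$tss >= 0 & g$tss < cfg$chrom_length))
})

test_that("the generator is seed-deterministic and rejects bad configs", {
  cfg <- simulation_config(n_pos = 2, n_neg = 2, n_unlabeled = 0, seed = 7)
  expect_identical(generate_universe(cfg), generate_universe(cfg))
  expect_identical(simulate_study(cfg), simulate_study(cfg))
  expect_error(simulation_config(n_pos = 0), "n_pos")
  expect_error(simulation_config(noise_sd = -1), "noise_sd")
  expect_error(simulation_config(p_peak_pos = 1.2), "p_peak_pos")
})

test_that("simulate_expression has the study shape and class signal", {
  sim <- quick_sim(seed = 2)
  expect_equal(dim(sim$expression), c(28, 79))
  expect_true(all(sim$expression > 0))
  expect_identical(colnames(sim$expression), study_layout()$name)

  # noiseless null: per-gene profiles are flat across all 79 conditions
  cfg0 <- simulation_config(n_pos = 5, n_neg = 5, n_unlabeled = 0,
                            effect_size = 0, noise_sd = 0, seed = 3)
  E0 <- simulate_expression(generate_universe(cfg0), config = cfg0)
  expect_equal(unname(apply(log2(E0), 1, sd)), rep(0, 10))

  # strong noiseless signal: complete ES-mean separation of the classes
  cfgS <- simulation_config(effect_size = 10, noise_sd = 0,
                            n_unlabeled = 0, seed = 4)
  gS <- generate_universe(cfgS)
  ES <- simulate_expression(gS, config = cfgS)[, "ES_mean"]
  expect_gt(min(ES[gS$label == "positive"]), max(ES[gS$label == "negative"]))

  bad_layout <- study_layout()[1:10, ]
  expect_error(simulate_expression(gS, bad_layout, cfgS), "79")
})

# NB: shared per-gene baselines make the 79 per-feature tests within one
# seed strongly correlated, so the rejection-rate estimator needs many
# seeds for a tight band (its per-seed s.d. is ~0.15)
test_that("null model rejects at about the nominal rate", {
  rates <- vapply(1:120, function(s) {
    cfg <- simulation_config(n_pos = 20, n_neg = 20, n_unlabeled = 0,
                             effect_size = 0, seed = 5000 + s)
    g <- generate_universe(cfg)
    E <- log2(simulate_expression(g, config = cfg))
    pos <- g$label == "positive"
    p <- vapply(seq_len(ncol(E)), function(j)
      stats::t.test(E[pos, j], E[!pos, j])$p.value, numeric(1))
    mean(p < 0.05)
  }, numeric(1))
  expect_gt(mean(rates), 0.02)
  expect_lt(mean(rates), 0.08)
})

test_that("simulate_chip_peaks plants class-dependent peaks per TF", {
  cfg <- simulation_config(n_pos = 8, n_neg = 8, n_unlabeled = 0,
                           p_peak_pos = 1, p_peak_neg = 0, seed = 5)
  g <- generate_universe(cfg)
  peaks <- simulate_chip_peaks(g, cfg)
  expect_length(peaks, 12)
  pos_ids <- g$gene_id[g$label == "positive"]
  neg_ids <- g$gene_id[g$label == "negative"]
  for (p in peaks) {
    expect_identical(names(p),
                     c("chrom", "start", "end", "tf", "intensity", "gene_id"))
    expect_setequal(p$gene_id, pos_ids)
    expect_length(intersect(p$gene_id, neg_ids), 0)
    expect_true(all(p$intensity > 0))
  }
  expect_identical(simulate_chip_peaks(g, cfg), peaks)
  cfg_inv <- simulation_config(p_peak_pos = 0.1, p_peak_neg = 0.9, seed = 5)
  expect_warning(simulate_chip_peaks(generate_universe(cfg_inv), cfg_inv),
                 "inverted")
})

test_that("candidate lists carry the configured enrichment and are disjoint", {
  cfg <- simulation_config(seed = 6)
  sim <- simulate_study(cfg)
  cand <- sim$candidates
  expect_length(cand$positive, 126)
  expect_length(cand$negative, 101)
  expect_length(intersect(cand$positive, cand$negative), 0)
  train <- sim$genes$gene_id[sim$genes$label != "unlabeled"]
  expect_length(intersect(c(cand$positive, cand$negative), train), 0)
  latent <- setNames(sim$genes$latent, sim$genes$gene_id)
  expect_equal(sum(latent[cand$positive] == "positive"),
               round(0.8 * 126))
  expect_true(all(latent[cand$negative] == "negative"))
})

test_that("write_fixtures round-trips and respects the file contracts", {
  sim <- quick_sim(seed = 8, n_unlabeled = 0)
  dir <- withr::local_tempdir()
  paths <- write_fixtures(sim$genes, sim$expression, sim$peaks, dir)

  g2 <- read_gene_bed(paths[["genes"]])
  expect_equal(g2$gene_id, sim$genes$gene_id)
  expect_equal(g2$tss, sim$genes$tss)

  E2 <- read_expression_tsv(paths[["expression"]])
  expect_equal(E2, sim$expression)
  expect_equal(ncol(read.table(paths[["expression"]], header = TRUE,
                               check.names = FALSE)), 80)

  pk <- read.table(paths[[paste0("peaks_", names(sim$peaks)[1])]],
                   sep = "\t")
  expect_equal(ncol(pk), 5)
  p2 <- read_peak_beds(paths[grepl("^peaks_", names(paths))])
  expect_equal(p2[[1]]$intensity, sim$peaks[[1]]$intensity)

  # byte-identical rerun
  dir2 <- withr::local_tempdir()
  sim_b <- quick_sim(seed = 8, n_unlabeled = 0)
  paths2 <- write_fixtures(sim_b$genes, sim_b$expression, sim_b$peaks, dir2)
  for (nm in names(paths))
    expect_identical(readLines(paths[[nm]]), readLines(paths2[[nm]]))

  expect_equal(read_gene_list(paths[["list_positive"]]),
               sim$genes$gene_id[sim$genes$label == "positive"])
})

test_that("YAML config round-trips", {
  cfg <- simulation_config(n_pos = 5, n_neg = 6, effect_size = 1.5, seed = 9)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, f)
  expect_equal(read_sim_config(f), cfg)
  writeLines("bogus_key: 1", f)
  expect_error(read_sim_config(f), "unknown configuration")
})
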