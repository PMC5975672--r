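# Synthetic-data generators: determinism, stated-world shape, ground truth.

test_that("generators are fully deterministic under the seed", {
  cfg <- sim_config(seed = 7)
  g1 <- gen_genome(cfg); g2 <- gen_genome(cfg)
  expect_identical(g1, g2)
  s1 <- gen_cnv_callset(cfg, g1$grid); s2 <- gen_cnv_callset(cfg, g2$grid)
  expect_identical(s1, s2)
  expect_identical(gen_wes_variants(cfg), gen_wes_variants(cfg))
  expect_identical(gen_phenotype_counts(cfg), gen_phenotype_counts(cfg))
  # a different seed changes the output
  expect_false(identical(gen_genome(sim_config(seed = 8)), g1))
})

test_that("generators restore the caller's RNG state", {
  set.seed(99)
  before <- .Random.seed
  invisible(gen_genome(sim_config(seed = 7)))
  expect_identical(.Random.seed, before)
})

test_that("gen_genome honours the configured world", {
  cfg <- sim_config(seed = 3, n_genes = 0L)
  g <- gen_genome(cfg)
  expect_equal(nrow(g$models$genes), 0L)
  expect_gt(length(unclass(g$grid)[["1"]]), 0L)

  # mean spacing within 5% at >= 10,000 markers (law of large numbers)
  cfg2 <- sim_config(seed = 4, marker_spacing_bp = 1000)
  g2 <- gen_genome(cfg2)
  pos <- unclass(g2$grid)[["2"]]  # chromosome without the probe-free zone
  expect_gte(length(pos), 5000L)
  expect_lt(abs(mean(diff(pos)) - 1000) / 1000, 0.05)

  # genes are non-overlapping with exons inside the span (validated by the
  # gene_models constructor; spot-check sortedness here)
  ex <- g2$models$exons
  one <- ex[ex$symbol == ex$symbol[1], ]
  expect_true(all(diff(one$start) > 0))

  expect_error(gen_genome(sim_config(seed = 1, n_genes = 5000L)),
               "infeasible packing")
})

test_that("gen_cnv_callset plants labelled truth with correct margins", {
  cfg <- sim_config(seed = 21)
  g <- gen_genome(cfg)
  sim <- gen_cnv_callset(cfg, g$grid)
  expect_setequal(unique(sim$calls$truth),
                  c("common_in_database", "rare", "fails_size",
                    "fails_markers", "seen_in_controls"))
  # the undersized decoy is below 50 kb but otherwise clean by construction
  fs <- sim$calls[sim$calls$truth == "fails_size", ]
  expect_lt(length_kb(fs), 50)
  expect_gte(fs$n_markers, 25)
  # the under-markered decoy sits in the probe-free zone
  fm <- sim$calls[sim$calls$truth == "fails_markers", ]
  expect_equal(fm$n_markers, 0L)
  expect_gt(length_kb(fm), 50)
  # spike-ins are wide of every threshold
  sp <- sim$calls[sim$calls$truth == "rare", ]
  expect_true(all(length_kb(sp) >= 250))
  expect_true(all(sp$n_markers >= 100))
  expect_error(gen_cnv_callset(cfg, g$grid,
                               spike_ins = data.frame(chrom = "2", start = 9.9e6,
                                                      end = 1.05e7,
                                                      copy_number = 3)),
               "outside chromosome bounds")
})

test_that("gen_wes_variants plants exactly the requested survivors", {
  cfg0 <- sim_config(seed = 5, planted_qualifying_variants = 0L)
  v0 <- gen_wes_variants(cfg0)
  expect_equal(sum(apply_variant_filter(v0)$qualifies), 0L)

  cfg6 <- sim_config(seed = 5, planted_qualifying_variants = 6L)
  v6 <- gen_wes_variants(cfg6)
  expect_equal(sum(v6$truth_qualifies), 6L)
  res <- apply_variant_filter(v6)
  expect_identical(res$qualifies, v6$truth_qualifies)
  # synonymous records never qualify
  expect_false(any(res$qualifies[res$consequence == "synonymous"]))
})

test_that("phenotype counts conserve embryos and honour degenerate probs", {
  cfg <- sim_config(seed = 9, phenotype_probs = list(
    allnorm = c(d_loop = 1, s_loop = 0, no_loop = 0),
    mixed = c(d_loop = 0.5, s_loop = 0.25, no_loop = 0.25)))
  ph <- gen_phenotype_counts(cfg)
  expect_true(all(rowSums(ph$allnorm$counts) == cfg$n_embryos_per_group))
  expect_true(all(ph$allnorm$counts[, c("s_loop", "no_loop")] == 0))
  expect_true(all(rowSums(ph$mixed$counts) == cfg$n_embryos_per_group))
  expect_error(sim_config(phenotype_probs = list(bad = c(d_loop = 0.5,
                                                         s_loop = 0.2,
                                                         no_loop = 0.2))),
               "sum to 1")
})
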