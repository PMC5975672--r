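# Four-criterion rarity filter.

test_that("is_common_vs_database implements the coverage-and-frequency rule", {
  p <- rare_filter_params()
  call <- one_call("1", 100000, 200000, cn = 3L)
  # not found in the database -> not common
  expect_false(is_common_vs_database(call, empty_common_cnv_db(), p))
  # 80% covered by a frequent same-dosage record -> common
  db_hot <- common_cnv_db("1", 100000, 180000, "gain", 0.05)
  expect_true(is_common_vs_database(call, db_hot, p))
  # same coverage but wrong dosage -> not common
  expect_false(is_common_vs_database(call, common_cnv_db("1", 100000, 180000,
                                                         "loss", 0.05), p))
  # same coverage but records themselves rare in the population -> not common
  expect_false(is_common_vs_database(call, common_cnv_db("1", 100000, 180000,
                                                         "gain", 1e-4), p))
  # exactly 50% coverage counts as common (>= boundary)
  expect_true(is_common_vs_database(call, common_cnv_db("1", 100000, 150000,
                                                        "gain", 0.05), p))
  expect_false(is_common_vs_database(call, common_cnv_db("1", 100000, 149999,
                                                         "gain", 0.05), p))
})

test_that("seen_in_controls uses 50% reciprocal overlap with matching dosage", {
  call <- one_call("1", 1000000, 1100000, cn = 1L)
  expect_false(seen_in_controls(call, list()))
  ident <- one_call("1", 1000000, 1100000, cn = 1L, sample = "N1")
  expect_true(seen_in_controls(call, list(ident)))
  # query nested in a 10x-larger control call fails the control->query direction
  big <- one_call("1", 600000, 1600000, cn = 1L, sample = "N1")
  expect_false(seen_in_controls(call, list(big)))
  # dosage must match
  gain <- one_call("1", 1000000, 1100000, cn = 3L, sample = "N1")
  expect_false(seen_in_controls(call, list(gain)))
})

test_that("apply_rare_filter assigns reason codes and errors without markers", {
  calls <- cnv_calls(c("1", "1"), c(1e6, 2e6), c(1e6 + 45e3, 2e6 + 60e3),
                     c(1L, 3L), c("A", "B"), n_markers = c(40L, 40L))
  dec <- apply_rare_filter(calls)
  expect_false(dec$rare[1])
  expect_equal(dec$reasons[1], "fails_size")
  expect_true(dec$rare[2])
  expect_equal(dec$reasons[2], "")

  nomark <- cnv_calls("1", 1e6, 2e6, 1L, "A")
  expect_error(apply_rare_filter(nomark), "no marker grid")
  g <- marker_grid(list("1" = seq(1e6, 2e6, by = 1e4)))
  expect_equal(apply_rare_filter(nomark, grid = g)$markers_used, 100L)
})

test_that("the published call set is entirely rare against empty references", {
  dec <- apply_rare_filter(htx_table2())
  expect_equal(nrow(dec), 19L)
  expect_true(all(dec$rare))
  expect_true(all(dec$reasons == ""))
})

test_that("filter equals the independent brute-force oracle on synthetic data", {
  for (seed in c(1, 17, 123)) {
    cfg <- sim_config(seed = seed)
    g <- gen_genome(cfg)
    sim <- gen_cnv_callset(cfg, g$grid)
    dec <- apply_rare_filter(sim$calls, sim$db, sim$cohorts, g$grid)
    for (i in seq_len(nrow(dec))) {
      why <- oracle_rarity_reasons(dec[i, ], sim$db, sim$cohorts)
      expect_equal(strsplit(dec$reasons[i], ",")[[1]], why,
                   info = sprintf("seed %d row %d", seed, i))
      expect_equal(dec$rare[i], length(why) == 0L)
    }
    # ground-truth recovery: rare calls are exactly the planted ones and
    # every decoy is rejected for exactly its planted reason
    expect_identical(dec$rare, sim$calls$truth == "rare")
    decoys <- dec$truth != "rare"
    expect_identical(dec$reasons[decoys], dec$truth[decoys])
  }
})

test_that("filter is monotone in thresholds and reference sets", {
  cfg <- sim_config(seed = 31)
  g <- gen_genome(cfg)
  sim <- gen_cnv_callset(cfg, g$grid)
  base <- apply_rare_filter(sim$calls, sim$db, sim$cohorts, g$grid)

  stricter_size <- apply_rare_filter(sim$calls, sim$db, sim$cohorts, g$grid,
                                     rare_filter_params(min_size_kb = 200))
  stricter_markers <- apply_rare_filter(sim$calls, sim$db, sim$cohorts, g$grid,
                                        rare_filter_params(min_markers = 200))
  expect_true(all(stricter_size$rare <= base$rare))
  expect_true(all(stricter_markers$rare <= base$rare))

  # enlarging the database or the cohorts never adds rare calls
  no_db <- apply_rare_filter(sim$calls, cohorts = sim$cohorts, grid = g$grid)
  expect_true(all(base$rare <= no_db$rare))
  no_ctrl <- apply_rare_filter(sim$calls, sim$db, grid = g$grid)
  expect_true(all(base$rare <= no_ctrl$rare))
})
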