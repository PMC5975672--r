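# Contingency statistics and cohort summaries.

test_that("collapse_to_2x2 pools replicates and sums abnormal categories", {
  treated <- phenotype_counts("mo", "looping",
                              c(d_loop = 70, s_loop = 15, no_loop = 15))
  control <- phenotype_counts("ctrl", "looping",
                              c(d_loop = 98, s_loop = 1, no_loop = 1))
  t2 <- collapse_to_2x2(treated, control)
  expect_equal(unname(t2), matrix(c(30, 2, 70, 98), 2, 2))

  # pooled replicates equal the sum of per-replicate tables
  m <- matrix(c(40, 30, 5, 10, 5, 10), nrow = 2,
              dimnames = list(NULL, c("d_loop", "s_loop", "no_loop")))
  reps <- phenotype_counts("mo", "looping", m)
  pooled <- collapse_to_2x2(reps, control)
  per_rep <- Reduce(`+`, lapply(1:2, function(r)
    collapse_to_2x2(phenotype_counts("mo", "looping", m[r, , drop = FALSE]),
                    phenotype_counts("z", "looping",
                                     c(d_loop = 0, s_loop = 0, no_loop = 0)))))
  expect_equal(pooled["treated", ], per_rep["treated", ])

  expr <- phenotype_counts("mo", "expression",
                           c(left = 50, right = 5, bilateral = 3, absent = 2))
  expect_equal(collapse_to_2x2(expr, expr)["treated", ],
               c(abnormal = 10L, normal = 50L))
  expect_error(collapse_to_2x2(treated, expr), "schemes differ")
})

test_that("Fisher p matches exhaustive hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(matrix(5, 2, 2))$p_value, 1.0)
  # closed-form check: 2*(C(10,0)C(10,10) + C(10,1)C(10,9)) / C(20,10)
  t <- matrix(c(1, 9, 9, 1), 2, 2)
  expect_equal(fisher_exact_2x2(t)$p_value, 202 / 184756, tolerance = 1e-12)
  expect_error(fisher_exact_2x2(matrix(0L, 2, 2)), "all-zero")

  set.seed(41)
  for (i in 1:300) {
    tt <- random_2x2(40)
    expect_equal(fisher_exact_2x2(tt)$p_value, oracle_fisher_p(tt),
                 tolerance = 1e-12, info = paste(tt, collapse = ","))
  }
  # and agreement with the reference implementation
  for (i in 1:25) {
    tt <- random_2x2(40)
    expect_equal(fisher_exact_2x2(tt)$p_value,
                 stats::fisher.test(tt)$p.value, tolerance = 1e-9)
  }
})

test_that("Yates statistic matches the closed form and reference", {
  expect_equal(chi2_yates_2x2(matrix(c(10, 10, 90, 90), 2, 2))$statistic, 0)
  expect_equal(chi2_yates_2x2(matrix(c(10, 10, 90, 90), 2, 2))$p_value, 1)

  t <- matrix(c(10, 30, 20, 40), 2, 2)
  N <- 100
  hand <- N * (abs(10 * 40 - 20 * 30) - N / 2)^2 / (30 * 70 * 40 * 60)
  r <- chi2_yates_2x2(t)
  expect_equal(r$statistic, hand, tolerance = 1e-12)
  ref <- stats::chisq.test(t, correct = TRUE)
  expect_equal(r$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-12)
  expect_error(chi2_yates_2x2(matrix(c(0, 0, 5, 5), 2, 2)), "zero margin")

  set.seed(42)
  for (i in 1:50) {
    tt <- random_2x2(200)
    got <- chi2_yates_2x2(tt)
    ref <- suppressWarnings(stats::chisq.test(tt, correct = TRUE))
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
    # corrected statistic never exceeds the uncorrected one
    expect_lte(got$statistic,
               unname(suppressWarnings(stats::chisq.test(tt, correct = FALSE))$statistic) + 1e-12)
  }
})

test_that("both tests are invariant under simultaneous row and column swaps", {
  set.seed(43)
  for (i in 1:40) {
    tt <- random_2x2(40)
    sw <- tt[2:1, 2:1]
    expect_equal(fisher_exact_2x2(tt)$p_value, fisher_exact_2x2(sw)$p_value,
                 tolerance = 1e-12)
    expect_equal(chi2_yates_2x2(tt)$statistic, chi2_yates_2x2(sw)$statistic,
                 tolerance = 1e-12)
  }
})

test_that("compare_groups selects the test and stars the p-value", {
  big_t <- phenotype_counts("mo", "looping",
                            c(d_loop = 60, s_loop = 20, no_loop = 20))
  big_c <- phenotype_counts("ctrl", "looping",
                            c(d_loop = 80, s_loop = 10, no_loop = 10))
  expect_equal(compare_groups(big_t, big_c)$test_used, "chi2_yates")
  small_t <- phenotype_counts("mo", "looping",
                              c(d_loop = 18, s_loop = 2, no_loop = 0))
  small_c <- phenotype_counts("ctrl", "looping",
                              c(d_loop = 20, s_loop = 0, no_loop = 0))
  expect_equal(compare_groups(small_t, small_c)$test_used, "fisher")

  expect_equal(htxcnv:::stars_of(0.03), "*")
  expect_equal(htxcnv:::stars_of(0.0005), "***")
  expect_equal(htxcnv:::stars_of(0.5), "ns")
  expect_equal(htxcnv:::stars_of(0.009), "**")
})

test_that("cohort percentages use half-up rounding to one decimal", {
  # binary-exact ties so the half-up behaviour itself is what is tested
  expect_equal(round_half_up(c(0.25, 0.75, -0.25), 1), c(0.3, 0.8, -0.3))
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(100 * 35 / 63, 1), 55.6)
  s <- summarize_cohort(c(male = 40, dextrocardia = 35, none = 0), 63)
  expect_equal(s$percent, c(63.5, 55.6, 0.0))
  expect_error(summarize_cohort(c(a = 70), 63), "exceeds denominator")
  expect_error(summarize_cohort(c(a = 1), 0), "positive")

  # every fixture percentage reproduces at the printed precision
  t1 <- htx_table1()
  s1 <- summarize_cohort(t1[, c("category", "count")], 63)
  printed <- c(63.5, 36.5, 23.8, 55.6, 20.6, 31.7, 52.4, 11.1, 9.5, 46.0,
               33.3, 11.1, 54.0, 11.1, 34.9, 27.0, 71.4, 1.6)
  expect_equal(s1$percent, printed)
})
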