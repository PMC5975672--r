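# Interval algebra: length convention, overlap, union coverage, markers.

test_that("length_bp reproduces printed segment sizes and rejects bad input", {
  # published coordinate pairs and their printed sizes
  iv <- genomic_intervals(c("1", "12"), c(145625128, 123357010),
                          c(145927662, 124310519))
  expect_equal(length_bp(iv), c(302534, 953509))
  expect_equal(length_kb(iv), c(302.534, 953.509))
  expect_equal(length_bp(genomic_intervals("3", 42, 42)), 0)
  expect_error(genomic_intervals("1", 100, 50), "end < start")
  expect_error(genomic_intervals("", 1, 2), "non-empty")
})

test_that("chromosome labels normalize consistently", {
  expect_equal(normalize_chrom(c("chr1", "1", "ChrX", "x")), c("1", "1", "X", "X"))
  a <- genomic_intervals("chr2", 100, 200)
  b <- genomic_intervals("2", 150, 300)
  expect_equal(overlap_bp(a, b), 50)
})

test_that("overlap_bp matches definition and per-base oracle", {
  a <- genomic_intervals("1", 100, 200)
  expect_equal(overlap_bp(a, genomic_intervals("1", 300, 400)), 0)
  expect_equal(overlap_bp(a, a), 100)
  expect_equal(overlap_bp(a, genomic_intervals("2", 100, 200)), 0)

  set.seed(11)
  for (i in 1:200) {
    x <- sort(sample(1:300, 2)); y <- sort(sample(1:300, 2))
    p <- genomic_intervals("1", x[1], x[2]); q <- genomic_intervals("1", y[1], y[2])
    expect_identical(overlap_bp(p, q), overlap_bp(q, p))
    expect_equal(overlap_bp(p, q), oracle_overlap_bp(p, q))
  }
})

test_that("coverage_fraction matches brute-force union and is monotone", {
  q <- genomic_intervals("1", 100, 200)
  expect_equal(coverage_fraction(q, genomic_intervals("1", 50, 400)), 1.0)
  expect_equal(coverage_fraction(q, genomic_intervals("2", 50, 400)), 0.0)
  expect_error(coverage_fraction(genomic_intervals("1", 5, 5),
                                 genomic_intervals("1", 1, 10)), "zero-length")

  # two partially overlapping refs, expected value from the per-base oracle
  refs <- genomic_intervals(c("1", "1"), c(80, 140), c(150, 170))
  expect_equal(coverage_fraction(q, refs), oracle_coverage_fraction(q, refs))
  expect_equal(coverage_fraction(q, refs), 0.7)

  set.seed(12)
  for (i in 1:100) {
    qq <- sort(sample(1:9999, 2)); if (qq[1] == qq[2]) next
    q2 <- genomic_intervals("1", qq[1], qq[2])
    nr <- sample(1:5, 1)
    rs <- t(replicate(nr, sort(sample(1:9999, 2))))
    refs2 <- genomic_intervals(rep("1", nr), rs[, 1], rs[, 2])
    expect_equal(coverage_fraction(q2, refs2),
                 oracle_coverage_fraction(q2, refs2), tolerance = 1e-12)
    # monotone non-decreasing as refs are added
    prev <- 0
    for (k in seq_len(nr)) {
      cur <- coverage_fraction(q2, refs2[1:k, , drop = FALSE])
      expect_gte(cur, prev - 1e-12)
      prev <- cur
    }
  }
})

test_that("reciprocal_overlap requires both directions", {
  small <- genomic_intervals("1", 1000, 1100)
  big <- genomic_intervals("1", 500, 1500)
  expect_true(reciprocal_overlap(small, small))
  expect_false(reciprocal_overlap(small, big))   # fails big -> small direction
  expect_false(reciprocal_overlap(big, small))
})

test_that("count_markers uses the half-open convention", {
  expect_equal(count_markers(genomic_intervals("1", 1, 100), marker_grid(list())), 0L)
  # uniform 1 kb grid, 100 kb segment aligned to the grid -> 100 markers
  g <- marker_grid(list("1" = seq(0, 999000, by = 1000)))
  expect_equal(count_markers(genomic_intervals("1", 0, 100000), g), 100L)
  # boundary: marker at end is excluded, marker at start included
  expect_equal(count_markers(genomic_intervals("1", 1000, 2000), g), 1L)
  # segment shorter than spacing: 0 or 1 depending on phase
  expect_equal(count_markers(genomic_intervals("1", 1500, 1900), g), 0L)
  expect_equal(count_markers(genomic_intervals("1", 900, 1300), g), 1L)
  expect_error(marker_grid(list("1" = c(5, 3))), "strictly increasing")
})
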