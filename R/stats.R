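# Contingency statistics for zebrafish laterality assays and cohort tables.
#
# Phenotype counts come in two schemes: heart-looping (d_loop, s_loop,
# no_loop) and marker expression (left, right, bilateral, absent). The first
# category of each scheme is the normal one; everything else is abnormal.
# Group comparisons collapse to a 2x2 table and use the Yates-corrected
# chi-squared test, falling back to Fisher's exact test when any expected
# cell is below 5.

PHENO_SCHEMES <- list(looping = c("d_loop", "s_loop", "no_loop"),
                      expression = c("left", "right", "bilateral", "absent"))

#' Construct phenotype counts
#'
#' @param group Group label (e.g. `"StdCtrl"`, `"numb_MO"`).
#' @param scheme `"looping"` or `"expression"`.
#' @param counts Named integer vector or matrix (replicates x categories)
#'   of embryo counts; names must match the scheme's categories. A vector is
#'   a single replicate.
#' @return List of class `phenotype_counts` with a replicate-by-category
#'   integer matrix.
#' @export
phenotype_counts <- function(group, scheme, counts) {
  scheme <- match.arg(scheme, names(PHENO_SCHEMES))
  cats <- PHENO_SCHEMES[[scheme]]
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1,
                                             dimnames = list(NULL, names(counts)))
  if (is.null(colnames(counts)) || !setequal(colnames(counts), cats)) {
    stop("counts must be named with the scheme categories: ",
         paste(cats, collapse = ", "))
  }
  counts <- counts[, cats, drop = FALSE]
  if (any(counts < 0) || anyNA(counts)) stop("counts must be non-negative")
  structure(list(group = as.character(group), scheme = scheme,
                 counts = matrix(as.integer(counts), nrow = nrow(counts),
                                 dimnames = list(NULL, cats))),
            class = "phenotype_counts")
}

#' Collapse two phenotype groups to a 2x2 abnormal/normal table
#'
#' Abnormal is the sum over all non-first categories (s_loop + no_loop, or
#' right + bilateral + absent); replicates are pooled by summation.
#'
#' @param treated,control [phenotype_counts()] with the same scheme.
#' @return 2x2 integer matrix, rows `treated`/`control`, columns
#'   `abnormal`/`normal`.
#' @export
collapse_to_2x2 <- function(treated, control) {
  stopifnot(inherits(treated, "phenotype_counts"),
            inherits(control, "phenotype_counts"))
  if (!identical(treated$scheme, control$scheme)) {
    stop("phenotype schemes differ: ", treated$scheme, " vs ", control$scheme)
  }
  row_of <- function(p) {
    tot <- colSums(p$counts)
    c(abnormal = sum(tot[-1]), normal = unname(tot[1]))
  }
  m <- rbind(treated = row_of(treated), control = row_of(control))
  storage.mode(m) <- "integer"
  m
}

stars_of <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

test_result <- function(test_used, statistic, p_value) {
  structure(list(test_used = test_used, statistic = statistic,
                 p_value = p_value, stars = stars_of(p_value)),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: %sp = %.4g (%s)\n", x$test_used,
              if (is.na(x$statistic)) "" else
                sprintf("X-squared = %.4g, ", x$statistic),
              x$p_value, x$stars))
  invisible(x)
}

check_2x2 <- function(t) {
  if (!is.matrix(t) || !all(dim(t) == 2L)) stop("need a 2x2 matrix")
  if (any(t < 0) || anyNA(t)) stop("cells must be non-negative")
  invisible(t)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Computes the two-sided p-value by summing hypergeometric point
#' probabilities (at fixed margins) not exceeding the observed table's, the
#' standard point-probability method (tables tied with the observed, up to a
#' 1e-7 relative tolerance, are included).
#'
#' @param t 2x2 integer matrix.
#' @return A `test_result` (statistic is `NA`).
#' @export
fisher_exact_2x2 <- function(t) {
  check_2x2(t)
  if (sum(t) == 0) stop("all-zero table")
  m <- sum(t[1, ])          # row-1 margin
  n <- sum(t[2, ])          # row-2 margin
  k <- sum(t[, 1])          # column-1 margin
  x <- t[1, 1]
  lo <- max(0, k - n); hi <- min(k, m)
  support <- lo:hi
  d <- stats::dhyper(support, m, n, k)
  p <- sum(d[d <= d[support == x] * (1 + 1e-7)])
  test_result("fisher", NA_real_, min(p, 1))
}

#' Yates continuity-corrected chi-squared test for a 2x2 table
#'
#' Statistic: `N * (max(|ad - bc| - N/2, 0))^2 / (r1 r2 c1 c2)`, compared to
#' the chi-squared distribution with 1 df. All margins must be positive.
#'
#' @param t 2x2 integer matrix.
#' @return A `test_result`.
#' @export
chi2_yates_2x2 <- function(t) {
  check_2x2(t)
  r <- rowSums(t); cc <- colSums(t); N <- sum(t)
  if (any(r == 0) || any(cc == 0)) stop("zero margin: chi-squared undefined")
  ad_bc <- abs(t[1, 1] * t[2, 2] - t[1, 2] * t[2, 1])
  stat <- N * max(ad_bc - N / 2, 0)^2 / prod(c(r, cc))
  test_result("chi2_yates", stat, stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Compare a treated group to its control
#'
#' Collapses both groups to a 2x2 abnormal/normal table and tests it:
#' Fisher's exact test when any expected cell count is below 5, otherwise the
#' Yates-corrected chi-squared test. Stars follow the 0.05/0.01/0.001
#' thresholds.
#'
#' @param treated,control [phenotype_counts()] with the same scheme.
#' @return A `test_result`.
#' @export
compare_groups <- function(treated, control) {
  t2 <- collapse_to_2x2(treated, control)
  expected <- outer(rowSums(t2), colSums(t2)) / sum(t2)
  if (any(expected < 5)) fisher_exact_2x2(t2) else chi2_yates_2x2(t2)
}

#' Summarize a cohort phenotype table with percentages
#'
#' Percentages are `100 * count / denominator`, rounded half-up to 1 decimal
#' (the convention that reproduces printed clinical tables).
#'
#' @param counts Named integer vector (or data.frame with `category` and
#'   `count` columns) of patient counts.
#' @param denominator Total number of patients (> 0).
#' @return data.frame with `category`, `count`, `percent`.
#' @export
summarize_cohort <- function(counts, denominator) {
  if (is.data.frame(counts)) {
    stopifnot(all(c("category", "count") %in% names(counts)))
    cat_ <- as.character(counts$category); n <- as.numeric(counts$count)
  } else {
    cat_ <- names(counts); n <- as.numeric(counts)
  }
  if (denominator <= 0) stop("denominator must be positive")
  if (any(n > denominator)) stop("count exceeds denominator")
  data.frame(category = cat_, count = as.integer(n),
             percent = round_half_up(100 * n / denominator, 1),
             stringsAsFactors = FALSE)
}

#' Round half-up
#'
#' Decimal rounding with ties going away from zero (unlike R's banker
#' rounding), matching how printed clinical percentages are rounded.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}
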