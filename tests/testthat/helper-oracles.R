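# Independent oracles used across the suite. These deliberately avoid the
# package's own interval algebra: small-coordinate cases are checked per
# base, large-coordinate cases through IRanges (1-based inclusive, so the
# half-open [start, end) interval maps to IRanges(start, end - 1)).

# Per-base covered positions of [start, end); only for small coordinates.
bases_of <- function(start, end) if (end > start) seq(start, end - 1) else integer(0)

oracle_overlap_bp <- function(a, b) {
  if (a$chrom != b$chrom) return(0L)
  length(intersect(bases_of(a$start, a$end), bases_of(b$start, b$end)))
}

oracle_coverage_fraction <- function(query, refs) {
  q <- bases_of(query$start, query$end)
  covered <- unique(unlist(lapply(seq_len(nrow(refs)), function(i) {
    if (refs$chrom[i] != query$chrom) return(integer(0))
    intersect(q, bases_of(refs$start[i], refs$end[i]))
  })))
  length(covered) / length(q)
}

# IRanges route for genome-scale coordinates.
ir_of <- function(df) IRanges::IRanges(start = df$start, end = df$end - 1)

oracle_coverage_fraction_ir <- function(query, refs) {
  refs <- refs[refs$chrom == query$chrom & refs$end > refs$start, , drop = FALSE]
  if (!nrow(refs)) return(0)
  inter <- IRanges::intersect(IRanges::reduce(ir_of(refs)), ir_of(query))
  sum(IRanges::width(inter)) / (query$end - query$start)
}

oracle_reciprocal <- function(a, b, thr = 0.5) {
  ov <- if (a$chrom == b$chrom)
    sum(IRanges::width(IRanges::intersect(ir_of(a), ir_of(b)))) else 0
  ov / (a$end - a$start) >= thr && ov / (b$end - b$start) >= thr
}

# Independent four-criterion re-evaluation of a single call.
oracle_rarity_reasons <- function(call, db, cohorts, p = rare_filter_params()) {
  why <- character(0)
  if (!((call$end - call$start) / 1000 > p$min_size_kb)) why <- c(why, "fails_size")
  if (!(call$n_markers >= p$min_markers)) why <- c(why, "fails_markers")
  hits <- db[db$dosage == call$dosage & db$frequency >= p$max_common_frequency, ]
  if (nrow(hits) &&
      oracle_coverage_fraction_ir(call, hits) >= p$max_common_coverage) {
    why <- c(why, "common_in_database")
  }
  seen <- FALSE
  for (co in cohorts) {
    for (j in seq_len(nrow(co))) {
      if (co$dosage[j] == call$dosage && co$chrom[j] == call$chrom &&
          oracle_reciprocal(call, co[j, ], p$reciprocal_threshold)) seen <- TRUE
    }
  }
  if (seen) why <- c(why, "seen_in_controls")
  why
}

# Per-gene/per-exon containment oracle for genic classification.
oracle_classify <- function(call, models) {
  g <- models$genes; e <- models$exons
  hits_exon <- FALSE
  for (j in seq_len(nrow(e))) {
    if (e$chrom[j] == call$chrom &&
        oracle_overlap_ir(call, e[j, ]) > 0) hits_exon <- TRUE
  }
  contains <- FALSE
  for (j in seq_len(nrow(g))) {
    if (g$chrom[j] == call$chrom && g$start[j] >= call$start &&
        g$end[j] <= call$end) contains <- TRUE
  }
  if (call$dosage == "loss") {
    if (hits_exon) "genic_del" else "noncoding"
  } else if (contains) "genic_dup"
  else if (hits_exon) "internal_dup"
  else "noncoding"
}

oracle_overlap_ir <- function(a, b) {
  if (a$chrom != b$chrom) return(0)
  sum(IRanges::width(IRanges::intersect(ir_of(a), ir_of(b))))
}

# Exhaustive hypergeometric enumeration of the two-sided Fisher p-value,
# using choose() only.
oracle_fisher_p <- function(t) {
  m <- sum(t[1, ]); n <- sum(t[2, ]); k <- sum(t[, 1]); x <- t[1, 1]
  support <- max(0, k - n):min(k, m)
  prob <- choose(m, support) * choose(n, k - support) / choose(m + n, k)
  p_obs <- prob[support == x]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

# Random valid 2x2 table with N <= n_max and positive margins.
random_2x2 <- function(n_max = 40) {
  repeat {
    cells <- as.vector(stats::rmultinom(1, sample(4:n_max, 1), rep(0.25, 4)))
    t <- matrix(cells, 2, 2)
    if (all(rowSums(t) > 0) && all(colSums(t) > 0)) return(t)
  }
}

tiny_models <- function() {
  gene_models(
    genes = data.frame(symbol = c("GA", "GB", "GC"), chrom = c("1", "1", "2"),
                       start = c(100, 1000, 100), end = c(500, 2000, 900),
                       strand = c("+", "-", "+")),
    exons = data.frame(symbol = c("GA", "GA", "GB", "GB", "GB", "GC"),
                       chrom = c("1", "1", "1", "1", "1", "2"),
                       start = c(120, 300, 1100, 1400, 1800, 200),
                       end = c(180, 400, 1200, 1500, 1900, 300)))
}

one_call <- function(chrom, start, end, cn = 1L, sample = "S1") {
  cnv_calls(chrom, start, end, cn, sample)
}
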