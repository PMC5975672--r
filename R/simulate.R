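# Seeded synthetic-data generators.
#
# Every input the pipeline consumes can be generated with ground-truth
# labels: a probe grid, non-overlapping gene models, a common-CNV database
# mirrored into per-sample background calls, spike-in rare CNVs, decoy calls
# each violating exactly one rarity criterion, annotated exome variant
# tables with planted qualifying variants, and multinomial phenotype counts.
# A fixed seed fully determines every output; generators restore the
# caller's RNG state.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulation configuration
#'
#' Defaults describe a deliberately tiny world (2 chromosomes of 10 Mb, 1 kb
#' mean probe spacing, 20 samples) so the full suite runs in seconds while
#' every planted event stays well clear of the filter thresholds.
#'
#' @param seed Integer seed; fully determines all generator output.
#' @param n_chromosomes,chrom_length_bp Genome shape.
#' @param marker_spacing_bp Mean probe spacing (exponential inter-probe gaps).
#' @param n_genes Number of non-overlapping gene models.
#' @param exons_per_gene Length-2 integer range of coding exons per gene.
#' @param n_common_cnvs Common-CNV database size.
#' @param common_freq_range Carrier-frequency range of database records
#'   (must sit at or above 0.001 so background calls are genuinely common).
#' @param n_samples Patient cohort size.
#' @param n_variants,planted_qualifying_variants Exome table shape.
#' @param phenotype_probs Named list of per-group category probability
#'   vectors (each summing to 1).
#' @param n_embryos_per_group,n_replicates Phenotype assay shape.
#' @param freq_is_carrier Whether database frequencies are carrier (default)
#'   rather than allele frequencies; annotation only, the filter is agnostic.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chrom_length_bp = 1e7,
                       marker_spacing_bp = 1000,
                       n_genes = 60L,
                       exons_per_gene = c(2L, 20L),
                       n_common_cnvs = 20L,
                       common_freq_range = c(0.005, 0.05),
                       n_samples = 20L,
                       n_variants = 200L,
                       planted_qualifying_variants = 6L,
                       phenotype_probs = list(
                         StdCtrl = c(d_loop = 0.98, s_loop = 0.01, no_loop = 0.01),
                         morphant = c(d_loop = 0.75, s_loop = 0.13, no_loop = 0.12)),
                       n_embryos_per_group = 80L,
                       n_replicates = 3L,
                       freq_is_carrier = TRUE) {
  stopifnot(n_chromosomes >= 1, chrom_length_bp > 1e6, marker_spacing_bp > 0,
            n_genes >= 0, length(exons_per_gene) == 2,
            exons_per_gene[1] >= 1, exons_per_gene[2] >= exons_per_gene[1],
            n_common_cnvs >= 0, length(common_freq_range) == 2,
            common_freq_range[1] >= 0.001, n_samples >= 1,
            n_variants >= 0, planted_qualifying_variants >= 0,
            planted_qualifying_variants <= n_variants,
            n_embryos_per_group > 0, n_replicates >= 1)
  for (p in phenotype_probs) {
    if (abs(sum(p) - 1) > 1e-9) stop("phenotype probability vectors must sum to 1")
  }
  structure(as.list(environment()), class = "sim_config")
}

# Probe-free zone carved out of chromosome 1 so the under-markered decoy has
# a home: [0.80, 0.815] of the chromosome length.
marker_gap <- function(cfg) {
  c(start = 0.80 * cfg$chrom_length_bp, end = 0.815 * cfg$chrom_length_bp)
}

#' Generate a probe grid and gene models
#'
#' Probe positions have exponential inter-probe gaps with the configured
#' mean; a fixed probe-free zone is carved out of chromosome 1 (for the
#' under-markered decoy of [gen_cnv_callset()]). Gene models are
#' non-overlapping, each with 2-20 sorted coding exons inside its span.
#'
#' @param cfg A [sim_config()].
#' @return List with `grid` ([marker_grid()]) and `models`
#'   ([gene_models()]).
#' @export
gen_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed + 101L, {
    chroms <- as.character(seq_len(cfg$n_chromosomes))
    gap <- marker_gap(cfg)
    positions <- lapply(chroms, function(chr) {
      n_exp <- ceiling(cfg$chrom_length_bp / cfg$marker_spacing_bp * 1.3)
      p <- cumsum(stats::rexp(n_exp, rate = 1 / cfg$marker_spacing_bp))
      p <- round(p[p < cfg$chrom_length_bp])
      if (chr == "1") p <- p[p < gap["start"] | p >= gap["end"]]
      unique(p)
    })
    names(positions) <- chroms
    grid <- marker_grid(positions)

    models <- NULL
    if (cfg$n_genes > 0) {
      per_chrom <- diff(round(seq(0, cfg$n_genes, length.out = cfg$n_chromosomes + 1)))
      glist <- list(); elist <- list(); gi <- 0L
      for (ci in seq_along(chroms)) {
        ng <- per_chrom[ci]
        if (ng == 0) next
        glen <- round(stats::runif(ng, 5e3, 5e4))
        slot <- cfg$chrom_length_bp / ng
        if (any(glen >= slot)) {
          stop("infeasible packing: too many genes for chromosome length")
        }
        gstart <- round((seq_len(ng) - 1) * slot +
                          stats::runif(ng, 0, slot - glen - 1)) + 1
        for (k in seq_len(ng)) {
          gi <- gi + 1L
          sym <- sprintf("SYNG%03d", gi)
          s <- gstart[k]; e <- s + glen[k]
          nex <- sample(cfg$exons_per_gene[1]:cfg$exons_per_gene[2], 1)
          # split the span into 2*nex+1 chunks; even chunks become exons
          cuts <- sort(stats::runif(2 * nex, s, e))
          ex_s <- round(cuts[seq(1, 2 * nex, by = 2)])
          ex_e <- round(cuts[seq(2, 2 * nex, by = 2)])
          keep <- ex_e > ex_s
          glist[[gi]] <- data.frame(symbol = sym, chrom = chroms[ci],
                                    start = s, end = e,
                                    strand = sample(c("+", "-"), 1),
                                    stringsAsFactors = FALSE)
          if (any(keep)) {
            elist[[gi]] <- data.frame(symbol = sym, chrom = chroms[ci],
                                      start = ex_s[keep], end = ex_e[keep],
                                      stringsAsFactors = FALSE)
          }
        }
      }
      models <- gene_models(do.call(rbind, glist), do.call(rbind, elist))
    } else {
      models <- gene_models(data.frame(symbol = character(0),
                                       chrom = character(0), start = numeric(0),
                                       end = numeric(0), strand = character(0)))
    }
    list(grid = grid, models = models)
  })
}

#' Generate CNV call sets with ground-truth rarity labels
#'
#' Builds (a) a common-CNV database whose records are mirrored into one
#' carrier sample each (truth label `common_in_database`), (b) spike-in rare
#' CNVs passing all four criteria by a wide margin (label `rare`), (c) one
#' decoy per criterion, each violating exactly that criterion (`fails_size`:
#' 45 kb; `fails_markers`: inside the probe-free zone; `common_in_database`:
#' fully covered by a 2% database record; `seen_in_controls`: mirrored into
#' a control cohort), and (d) two control cohorts with their own private
#' calls.
#'
#' @param cfg A [sim_config()].
#' @param grid The [marker_grid()] from [gen_genome()].
#' @param spike_ins Optional data.frame (`chrom`, `start`, `end`,
#'   `copy_number`) of rare events to plant; defaults to three events of
#'   250-400 kb on chromosome 2.
#' @return List with `calls` (patient call table with a `truth` column),
#'   `db`, `cohorts` (list of two call tables).
#' @export
gen_cnv_callset <- function(cfg, grid, spike_ins = NULL) {
  stopifnot(inherits(cfg, "sim_config"), inherits(grid, "marker_grid"))
  L <- cfg$chrom_length_bp
  chrom2 <- as.character(min(2L, cfg$n_chromosomes))
  if (is.null(spike_ins)) {
    spike_ins <- data.frame(chrom = chrom2,
                            start = c(1.0e6, 2.0e6, 3.0e6),
                            end = c(1.3e6, 2.25e6, 3.4e6),
                            copy_number = c(3L, 1L, 4L),
                            stringsAsFactors = FALSE)
  }
  if (any(spike_ins$end > L) || any(spike_ins$start < 1)) {
    stop("spike-in outside chromosome bounds")
  }
  with_seed(cfg$seed + 202L, {
    samples <- sprintf("P%02d", seq_len(cfg$n_samples))
    gap <- marker_gap(cfg)

    # --- common database on chromosome 1, non-overlapping slots
    db <- empty_common_cnv_db()
    calls <- list()
    if (cfg$n_common_cnvs > 0) {
      slot <- (0.75 * L) / cfg$n_common_cnvs
      len <- round(stats::runif(cfg$n_common_cnvs, 6e4, min(4e5, slot - 1e3)))
      s <- round((seq_len(cfg$n_common_cnvs) - 1) * slot +
                   stats::runif(cfg$n_common_cnvs, 0, slot - len - 500)) + 1
      db <- common_cnv_db(chrom = rep("1", cfg$n_common_cnvs),
                          start = s, end = s + len,
                          dosage = sample(c("gain", "loss"),
                                          cfg$n_common_cnvs, replace = TRUE),
                          frequency = stats::runif(cfg$n_common_cnvs,
                                                   cfg$common_freq_range[1],
                                                   cfg$common_freq_range[2]))
      carrier <- sample(samples, cfg$n_common_cnvs, replace = TRUE)
      calls[[1]] <- data.frame(chrom = db$chrom, start = db$start, end = db$end,
                               copy_number = ifelse(db$dosage == "loss", 1L, 3L),
                               sample_id = carrier,
                               truth = "common_in_database",
                               stringsAsFactors = FALSE)
    }

    # --- rare spike-ins
    calls[[length(calls) + 1L]] <- data.frame(
      chrom = spike_ins$chrom, start = spike_ins$start, end = spike_ins$end,
      copy_number = as.integer(spike_ins$copy_number),
      sample_id = sample(samples, nrow(spike_ins), replace = FALSE),
      truth = "rare", stringsAsFactors = FALSE)

    # --- decoys, one per criterion
    decoy <- function(chrom, start, end, cn, label) {
      data.frame(chrom = chrom, start = start, end = end,
                 copy_number = cn, sample_id = sample(samples, 1),
                 truth = label, stringsAsFactors = FALSE)
    }
    calls[[length(calls) + 1L]] <- decoy(chrom2, 4.0e6, 4.045e6, 3L, "fails_size")
    calls[[length(calls) + 1L]] <- decoy("1", gap["start"] + 2e4,
                                         gap["start"] + 8e4, 1L, "fails_markers")
    common_decoy <- decoy(chrom2, 5.0e6, 5.2e6, 3L, "common_in_database")
    db <- rbind(db, common_cnv_db(chrom2, 5.0e6, 5.2e6, "gain", 0.02))
    calls[[length(calls) + 1L]] <- common_decoy
    control_decoy <- decoy(chrom2, 6.0e6, 6.15e6, 1L, "seen_in_controls")
    calls[[length(calls) + 1L]] <- control_decoy

    calls <- do.call(rbind, calls)
    out_calls <- cnv_calls(calls$chrom, calls$start, calls$end,
                           calls$copy_number, calls$sample_id)
    out_calls$n_markers <- count_markers(out_calls, grid)
    out_calls$truth <- calls$truth

    # --- control cohorts: the planted match plus private calls at 7-9 Mb
    mk_cohort <- function(tag, n_private, planted = NULL) {
      s <- round(stats::runif(n_private, 7.0e6, 8.8e6))
      df <- data.frame(chrom = chrom2, start = s,
                       end = s + round(stats::runif(n_private, 6e4, 2e5)),
                       copy_number = sample(c(1L, 3L), n_private, replace = TRUE),
                       sample_id = sprintf("%s%02d", tag, seq_len(n_private)),
                       stringsAsFactors = FALSE)
      if (!is.null(planted)) df <- rbind(df, planted)
      co <- cnv_calls(df$chrom, df$start, df$end, df$copy_number, df$sample_id)
      co$n_markers <- count_markers(co, grid)
      co
    }
    planted <- data.frame(chrom = control_decoy$chrom,
                          start = control_decoy$start, end = control_decoy$end,
                          copy_number = control_decoy$copy_number,
                          sample_id = "N01", stringsAsFactors = FALSE)
    cohorts <- list(normals = mk_cohort("N", 8, planted),
                    nonhtx = mk_cohort("D", 8))
    list(calls = out_calls, db = db, cohorts = cohorts)
  })
}

#' Generate an annotated exome variant table with planted survivors
#'
#' Exactly `cfg$planted_qualifying_variants` rows satisfy all five filter
#' criteria; every other row is built to violate exactly one criterion,
#' chosen round-robin, so reject reason codes are individually testable.
#'
#' @param cfg A [sim_config()].
#' @param genes Gene symbols to draw from (default synthetic symbols).
#' @return data.frame in the [apply_variant_filter()] contract with an extra
#'   logical `truth_qualifies` column.
#' @export
gen_wes_variants <- function(cfg, genes = sprintf("SYNG%03d", 1:20)) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_variants; q <- cfg$planted_qualifying_variants
  with_seed(cfg$seed + 303L, {
    passing_row <- function() {
      data.frame(
        gene = sample(genes, 1),
        region_class = sample(c("exonic", "splicing"), 1, prob = c(0.9, 0.1)),
        consequence = sample(FUNCTIONAL_CONSEQUENCES, 1),
        freq_1000g = sample(c(NA, stats::runif(1, 0, 5e-4)), 1),
        freq_exac = sample(c(NA, stats::runif(1, 0, 5e-4)), 1),
        in_inhouse_controls = FALSE, in_nonhtx_patients = FALSE,
        n_deleterious_calls = sample(1:3, 1),
        zygosity = sample(c("het", "hom"), 1, prob = c(0.95, 0.05)),
        stringsAsFactors = FALSE)
    }
    rows <- lapply(seq_len(n), function(i) passing_row())
    qualify <- rep(FALSE, n)
    if (q > 0) qualify[sample.int(n, q)] <- TRUE
    breakers <- c("region", "synonymous", "frequency", "inhouse", "predictors")
    bi <- 0L
    for (i in which(!qualify)) {
      bi <- bi + 1L
      switch(breakers[(bi - 1L) %% 5L + 1L],
             region = { rows[[i]]$region_class <- "other" },
             synonymous = { rows[[i]]$consequence <- "synonymous" },
             frequency = {
               which_db <- sample(c("freq_1000g", "freq_exac", "both"), 1)
               f <- stats::runif(1, 0.002, 0.2)
               if (which_db != "freq_exac") rows[[i]]$freq_1000g <- f
               if (which_db != "freq_1000g") rows[[i]]$freq_exac <- f
             },
             inhouse = {
               if (stats::runif(1) < 0.5) rows[[i]]$in_inhouse_controls <- TRUE
               else rows[[i]]$in_nonhtx_patients <- TRUE
             },
             predictors = { rows[[i]]$n_deleterious_calls <- 0L })
    }
    out <- do.call(rbind, rows)
    out$truth_qualifies <- qualify
    out
  })
}

#' Generate multinomial phenotype counts per group
#'
#' One replicate-by-category count matrix per group in
#' `cfg$phenotype_probs`, each replicate a multinomial draw of
#' `cfg$n_embryos_per_group` embryos.
#'
#' @param cfg A [sim_config()].
#' @param scheme `"looping"` or `"expression"`; must match the category
#'   names of `cfg$phenotype_probs`.
#' @return Named list of [phenotype_counts()].
#' @export
gen_phenotype_counts <- function(cfg, scheme = "looping") {
  stopifnot(inherits(cfg, "sim_config"))
  cats <- PHENO_SCHEMES[[match.arg(scheme, names(PHENO_SCHEMES))]]
  with_seed(cfg$seed + 404L, {
    out <- lapply(names(cfg$phenotype_probs), function(g) {
      p <- cfg$phenotype_probs[[g]]
      if (!setequal(names(p), cats)) {
        stop("phenotype_probs categories do not match scheme '", scheme, "'")
      }
      m <- t(stats::rmultinom(cfg$n_replicates, cfg$n_embryos_per_group, p[cats]))
      colnames(m) <- cats
      phenotype_counts(g, scheme, m)
    })
    names(out) <- names(cfg$phenotype_probs)
    out
  })
}
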