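# End-to-end orchestration: rarity filter -> genic classification ->
# candidate prioritization -> (optional) exome variant filter -> cohort
# summaries, with a machine-readable run manifest.

#' Pipeline configuration
#'
#' Inputs may be given as in-memory objects or file paths (paths are read
#' with the corresponding reader at run time).
#'
#' @param calls Call table or path ([read_cnv_tsv()]).
#' @param db Common-CNV database, path, or `NULL` (empty).
#' @param cohorts List of control call tables / paths (may be empty).
#' @param models [gene_models()] or GFF3 path; `NULL` if `calls` already
#'   carry `impact_class` and `genes_altered` columns (pre-annotated input).
#' @param gene_sets [curated_gene_sets()]; default [htx_gene_sets()].
#' @param variants Optional variant table or path ([read_variants_tsv()]).
#' @param grid Optional [marker_grid()] or path.
#' @param rare_params,variant_params Filter parameter objects.
#' @param denominator Number of arrayed subjects for the carrier rate
#'   (an upstream QC fact, not recomputable from the call table).
#' @param out_dir Optional directory for TSV reports and `manifest.json`.
#' @param seed Seed recorded in the manifest.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(calls, db = NULL, cohorts = list(), models = NULL,
                            gene_sets = htx_gene_sets(), variants = NULL,
                            grid = NULL,
                            rare_params = rare_filter_params(),
                            variant_params = variant_filter_params(),
                            denominator = NULL, out_dir = NULL, seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

load_if_path <- function(x, reader) {
  if (is.character(x) && length(x) == 1L) reader(x) else x
}

#' Run the full pipeline
#'
#' Stages: (1) four-criterion rarity filter; (2) genic-impact
#' classification (skipped when calls are pre-annotated); (3) known-gene
#' screen and candidate prioritization over the rare subset; (4) optional
#' exome variant filter; (5) class tally and carrier-rate summary. Any
#' stage error aborts with the stage name.
#'
#' @param cfg A [pipeline_config()].
#' @return List of class `htx_report`: `decisions`, `impacts` (rare subset),
#'   `class_tally`, `known_gene_hits`, `candidates`, `variants`,
#'   `carrier_summary`, `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  calls <- stage("load_calls", load_if_path(cfg$calls, read_cnv_tsv))
  db <- stage("load_db", {
    d <- load_if_path(cfg$db, read_common_cnv_tsv)
    if (is.null(d)) empty_common_cnv_db() else d
  })
  cohorts <- stage("load_cohorts",
                   lapply(cfg$cohorts, load_if_path, reader = read_cnv_tsv))
  grid <- stage("load_grid", load_if_path(cfg$grid, read_marker_grid_tsv))
  models <- stage("load_models", load_if_path(cfg$models, read_gene_models_gff3))

  decisions <- stage("rarity_filter",
                     apply_rare_filter(calls, db, cohorts, grid, cfg$rare_params))
  rare <- decisions[decisions$rare, , drop = FALSE]

  impacts <- stage("classify", {
    if (!is.null(models)) classify_cnvs(rare, models)
    else if (all(c("impact_class", "genes_altered") %in% names(rare))) rare
    else stop("no gene models supplied and calls are not pre-annotated")
  })
  tally <- tabulate_classes(impacts)
  known <- stage("known_gene_screen", screen_known_genes(impacts, cfg$gene_sets))
  candidates <- stage("prioritize", select_candidates(impacts, cfg$gene_sets))

  variants <- NULL
  if (!is.null(cfg$variants)) {
    variants <- stage("variant_filter", {
      v <- load_if_path(cfg$variants, read_variants_tsv)
      apply_variant_filter(v, cfg$variant_params)
    })
  }

  carriers <- unique(impacts$sample_id)
  carrier_summary <- if (!is.null(cfg$denominator)) {
    summarize_cohort(stats::setNames(length(carriers), "rare_cnv_carriers"),
                     cfg$denominator)
  } else NULL

  manifest <- list(
    seed = cfg$seed,
    n_calls = nrow(calls), n_rare = nrow(rare),
    n_carriers = length(carriers), denominator = cfg$denominator,
    rare_params = unclass(cfg$rare_params),
    variant_params = unclass(cfg$variant_params),
    class_tally = as.list(tally),
    n_candidates = length(unique(candidates$symbol)),
    input_digest = digest_inputs(calls, db))

  report <- structure(list(decisions = decisions, impacts = impacts,
                           class_tally = tally, known_gene_hits = known,
                           candidates = candidates, variants = variants,
                           carrier_summary = carrier_summary,
                           manifest = manifest),
                      class = "htx_report")
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

digest_inputs <- function(calls, db) {
  tf <- tempfile()
  on.exit(unlink(tf))
  utils::write.table(calls, tf, sep = "\t", row.names = FALSE)
  d1 <- unname(tools::md5sum(tf))
  utils::write.table(db, tf, sep = "\t", row.names = FALSE)
  c(calls = d1, db = unname(tools::md5sum(tf)))
}

#' Write a report bundle to a directory
#'
#' Emits `decisions.tsv`, `impacts.tsv` (rare calls with class and genes,
#' mirroring the published table layout), `candidates.tsv`,
#' `class_tally.tsv`, optional `variants.tsv` / `carrier_summary.tsv`, and
#' `manifest.json`.
#'
#' @param report An `htx_report`.
#' @param dir Output directory (created if needed).
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "htx_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_cnv_tsv(report$decisions, p("decisions.tsv"))
  write_cnv_tsv(report$impacts, p("impacts.tsv"))
  write_tsv_plain(report$candidates, p("candidates.tsv"))
  write_tsv_plain(data.frame(impact_class = names(report$class_tally),
                             n = as.integer(report$class_tally)),
                  p("class_tally.tsv"))
  if (!is.null(report$variants)) write_variants_tsv(report$variants, p("variants.tsv"))
  if (!is.null(report$carrier_summary)) {
    write_tsv_plain(report$carrier_summary, p("carrier_summary.tsv"))
  }
  jsonlite::write_json(report$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.htx_report <- function(x, ...) {
  t <- x$class_tally
  cat(sprintf(paste0(
    "Rare-CNV report: %d/%d calls rare in %d carriers\n",
    "  classes: %d genic del, %d full-gene dup, %d internal dup, %d noncoding\n",
    "  candidates: %d gene(s) in %d segment(s) from %d patient(s)\n",
    "  known heterotaxy genes hit: %d\n"),
    sum(x$decisions$rare), nrow(x$decisions), x$manifest$n_carriers,
    t[["genic_del"]], t[["genic_dup"]], t[["internal_dup"]], t[["noncoding"]],
    length(unique(x$candidates$symbol)),
    nrow(unique(x$candidates[, c("chrom", "start", "end")])),
    length(unique(x$candidates$sample_id)),
    nrow(x$known_gene_hits)))
  invisible(x)
}
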