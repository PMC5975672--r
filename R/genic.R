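# Genic-impact classification of rare CNVs.
#
# Classes: a loss hitting >= 1 coding exon is a genic deletion; a gain fully
# containing >= 1 gene span is a full-gene duplication; a gain touching
# coding exons without containing any whole gene is an internal duplication;
# anything else is noncoding. Full-gene containment is tested against the
# gene SPAN (transcription unit), not the coding exons, so non-coding RNAs
# count as duplicated genes.

#' Construct a gene model set
#'
#' @param genes data.frame with columns `symbol`, `chrom`, `start`, `end`,
#'   `strand` (`+`/`-`; optional, defaults to `+`).
#' @param exons data.frame with columns `symbol`, `chrom`, `start`, `end`
#'   giving coding exons; exons must lie within the parent span and be
#'   non-overlapping. May be empty (e.g. non-coding genes).
#' @return A list of class `gene_models` with elements `genes` and `exons`
#'   (exons sorted by gene and position).
#' @export
gene_models <- function(genes, exons = NULL) {
  stopifnot(all(c("symbol", "chrom", "start", "end") %in% names(genes)))
  genes$chrom <- normalize_chrom(genes$chrom)
  genes$symbol <- as.character(genes$symbol)
  if (is.null(genes$strand)) genes$strand <- "+"
  validate_intervals(genes)
  if (anyDuplicated(genes$symbol)) stop("duplicate gene symbols in model set")
  if (is.null(exons) || nrow(exons) == 0L) {
    exons <- data.frame(symbol = character(0), chrom = character(0),
                        start = numeric(0), end = numeric(0),
                        stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("symbol", "chrom", "start", "end") %in% names(exons)))
    exons$chrom <- normalize_chrom(exons$chrom)
    exons$symbol <- as.character(exons$symbol)
    validate_intervals(exons)
    orphan <- setdiff(exons$symbol, genes$symbol)
    if (length(orphan)) stop("exons reference unknown genes: ",
                             paste(orphan, collapse = ", "))
    exons <- exons[order(exons$symbol, exons$start), , drop = FALSE]
    for (sym in unique(exons$symbol)) {
      ex <- exons[exons$symbol == sym, , drop = FALSE]
      g <- genes[genes$symbol == sym, , drop = FALSE]
      if (any(ex$chrom != g$chrom) || any(ex$start < g$start) || any(ex$end > g$end)) {
        stop(sprintf("exons of %s fall outside the gene span", sym))
      }
      if (nrow(ex) > 1L && any(ex$start[-1] < ex$end[-nrow(ex)])) {
        stop(sprintf("coding exons of %s overlap", sym))
      }
    }
  }
  rownames(genes) <- NULL; rownames(exons) <- NULL
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' Genes altered by a CNV call
#'
#' Every gene whose span overlaps the call interval (`overlap_bp > 0`),
#' reported left-to-right by start coordinate.
#'
#' @param call A single-row CNV call (or any single-row interval table).
#' @param models A [gene_models()] set.
#' @return Character vector of gene symbols in genomic order.
#' @export
genes_altered <- function(call, models) {
  stopifnot(inherits(models, "gene_models"), nrow(call) == 1L)
  g <- models$genes
  hit <- g$chrom == call$chrom & g$start < call$end & g$end > call$start
  g <- g[hit, , drop = FALSE]
  g$symbol[order(g$start)]
}

#' Classify the genic impact of a CNV call
#'
#' @param call A single-row CNV call table with `dosage` (or `copy_number`).
#' @param models A [gene_models()] set.
#' @return A list with `impact_class` (one of `genic_del`, `genic_dup`,
#'   `internal_dup`, `noncoding`) and `genes_altered` (character vector).
#' @export
classify_cnv <- function(call, models) {
  stopifnot(nrow(call) == 1L)
  if (is.null(call$dosage)) call$dosage <- dosage_of(call$copy_number)
  if (!is.na(call$copy_number) && call$copy_number == 2L) {
    stop("copy_number 2 is diploid, not a CNV")
  }
  genes <- models$genes
  exons <- models$exons
  hits_exon <- any(exons$chrom == call$chrom &
                     exons$start < call$end & exons$end > call$start)
  contains_gene <- any(genes$chrom == call$chrom &
                         genes$start >= call$start & genes$end <= call$end)
  cls <- if (call$dosage == "loss") {
    if (hits_exon) "genic_del" else "noncoding"
  } else {
    if (contains_gene) "genic_dup"
    else if (hits_exon) "internal_dup"
    else "noncoding"
  }
  list(impact_class = cls, genes_altered = genes_altered(call, models))
}

#' Classify every call in a table
#'
#' @param calls CNV call table.
#' @param models A [gene_models()] set.
#' @return `calls` with added columns `impact_class` and `genes_altered`
#'   (comma-joined symbols in genomic order).
#' @export
classify_cnvs <- function(calls, models) {
  validate_cnv_calls(calls)
  res <- lapply(seq_len(nrow(calls)),
                function(i) classify_cnv(calls[i, , drop = FALSE], models))
  out <- calls
  out$impact_class <- vapply(res, `[[`, character(1), "impact_class")
  out$genes_altered <- vapply(res, function(r)
    paste(r$genes_altered, collapse = ","), character(1))
  out
}

#' Tally impact classes
#'
#' @param impacts A data.frame with an `impact_class` column (or a character
#'   vector of classes).
#' @return Named integer vector over all four classes (zeros included).
#' @export
tabulate_classes <- function(impacts) {
  cls <- if (is.data.frame(impacts)) impacts$impact_class else as.character(impacts)
  lv <- c("genic_del", "genic_dup", "internal_dup", "noncoding")
  bad <- setdiff(unique(cls), lv)
  if (length(bad)) stop("unknown impact class: ", paste(bad, collapse = ", "))
  table(factor(cls, levels = lv)) |> c()
}
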