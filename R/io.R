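# Readers and writers for the on-disk formats, plus bundled fixtures.
#
# The canonical CNV exchange format is a BED-derived TSV (header row,
# tab-separated, positions as printed, thousands separators tolerated on
# read and never written). Readers validate row-by-row and report line
# numbers; writers emit stable column order and plain "\n" line endings.

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing column(s): %s", path, paste(miss, collapse = ", ")))
  }
  df
}

strip_thousands <- function(x) as.numeric(gsub(",", "", as.character(x)))

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Read / write CNV call tables
#'
#' Expected columns: `chrom`, `start`, `end`, `copy_number`, `sample_id`,
#' and optionally `n_markers`. Thousands separators in coordinates are
#' tolerated on read. Malformed rows (end < start, diploid copy number) are
#' rejected with their line context.
#'
#' @param path TSV file path.
#' @return A validated call table (see [cnv_calls()]).
#' @export
read_cnv_tsv <- function(path) {
  df <- read_tsv_checked(path, c("chrom", "start", "end", "copy_number", "sample_id"))
  df$start <- strip_thousands(df$start)
  df$end <- strip_thousands(df$end)
  for (i in seq_len(nrow(df))) {
    if (is.na(df$start[i]) || is.na(df$end[i]) || df$end[i] < df$start[i]) {
      stop(sprintf("%s row %d: malformed coordinates", path, i))
    }
    if (is.na(df$copy_number[i]) || df$copy_number[i] == 2) {
      stop(sprintf("%s row %d: copy_number must be a non-diploid integer", path, i))
    }
  }
  calls <- cnv_calls(df$chrom, df$start, df$end, df$copy_number, df$sample_id,
                     n_markers = if ("n_markers" %in% names(df)) df$n_markers
                     else NA_integer_)
  extra <- setdiff(names(df), names(calls))
  for (col in extra) calls[[col]] <- df[[col]]
  calls
}

#' @param calls Call table to write.
#' @rdname read_cnv_tsv
#' @export
write_cnv_tsv <- function(calls, path) {
  validate_cnv_calls(calls)
  front <- c("chrom", "start", "end", "copy_number", "dosage", "n_markers",
             "sample_id")
  cols <- c(front[front %in% names(calls)], setdiff(names(calls), front))
  df <- calls[, cols, drop = FALSE]
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  write_tsv_plain(df, path)
}

#' Read / write a common-CNV database table
#'
#' Columns: `chrom`, `start`, `end`, `dosage` (`gain`/`loss`), `frequency`
#' (carrier fraction in `[0,1]`).
#'
#' @param path TSV file path.
#' @return A [common_cnv_db()] table.
#' @export
read_common_cnv_tsv <- function(path) {
  df <- read_tsv_checked(path, c("chrom", "start", "end", "dosage", "frequency"))
  common_cnv_db(df$chrom, strip_thousands(df$start), strip_thousands(df$end),
                df$dosage, df$frequency)
}

#' @param db Database table to write.
#' @rdname read_common_cnv_tsv
#' @export
write_common_cnv_tsv <- function(db, path) {
  df <- db
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  write_tsv_plain(df, path)
}

#' Read / write gene models as GFF3
#'
#' A GFF3 subset: `gene` features with an `ID=` (or `Name=`) attribute
#' carrying the symbol, and `CDS`/`exon` children with a `Parent=`
#' attribute. GFF3 1-based inclusive coordinates are converted to the
#' internal half-open convention on read (`end + 1`) and back on write.
#'
#' @param path GFF3 file path.
#' @return A [gene_models()] set.
#' @export
read_gene_models_gff3 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- as.data.frame(rtracklayer::readGFF(path))
  first_of <- function(x) {
    if (is.list(x)) vapply(x, function(v)
      if (length(v)) as.character(v[[1]]) else NA_character_, character(1))
    else as.character(x)
  }
  chrom <- as.character(df$seqid)
  type <- as.character(df$type)
  # GFF3 is 1-based inclusive; internal convention measures length as
  # end - start, so shift ends by +1 on read.
  start <- as.numeric(df$start); end <- as.numeric(df$end) + 1
  is_gene <- type == "gene"
  if (!any(is_gene)) stop(path, ": no gene features")
  gsym <- first_of(df$ID)[is_gene]
  if ("Name" %in% names(df)) {
    alt <- first_of(df$Name)[is_gene]
    gsym[is.na(gsym)] <- alt[is.na(gsym)]
  }
  if (anyNA(gsym)) stop(path, ": gene feature without ID/Name attribute")
  genes <- data.frame(symbol = gsym, chrom = chrom[is_gene],
                      start = start[is_gene], end = end[is_gene],
                      strand = as.character(df$strand)[is_gene],
                      stringsAsFactors = FALSE)
  is_ex <- type %in% c("CDS", "exon")
  parent <- if ("Parent" %in% names(df)) first_of(df$Parent)[is_ex] else
    rep(NA_character_, sum(is_ex))
  if (any(is_ex) && anyNA(parent)) stop(path, ": exon/CDS without Parent attribute")
  exons <- data.frame(symbol = parent, chrom = chrom[is_ex],
                      start = start[is_ex], end = end[is_ex],
                      stringsAsFactors = FALSE)
  orphan <- setdiff(exons$symbol, genes$symbol)
  if (length(orphan)) stop(path, ": orphan exon(s) under ",
                           paste(orphan, collapse = ", "))
  gene_models(genes, exons)
}

#' @param models Gene models to write.
#' @rdname read_gene_models_gff3
#' @export
write_gene_models_gff3 <- function(models, path) {
  stopifnot(inherits(models, "gene_models"))
  g <- models$genes; e <- models$exons
  lines <- c("##gff-version 3",
             sprintf("%s\thtxcnv\tgene\t%.0f\t%.0f\t.\t%s\t.\tID=%s",
                     g$chrom, g$start, g$end - 1, g$strand, g$symbol))
  if (nrow(e)) {
    strand <- g$strand[match(e$symbol, g$symbol)]
    lines <- c(lines,
               sprintf("%s\thtxcnv\tCDS\t%.0f\t%.0f\t.\t%s\t.\tParent=%s",
                       e$chrom, e$start, e$end - 1, strand, e$symbol))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a marker grid
#'
#' Two columns: `chrom`, `position`.
#'
#' @param path TSV file path.
#' @return A [marker_grid()].
#' @export
read_marker_grid_tsv <- function(path) {
  df <- read_tsv_checked(path, c("chrom", "position"))
  pos <- split(strip_thousands(df$position), normalize_chrom(df$chrom))
  marker_grid(lapply(pos, function(p) sort(unique(p))))
}

#' @param grid Grid to write.
#' @rdname read_marker_grid_tsv
#' @export
write_marker_grid_tsv <- function(grid, path) {
  stopifnot(inherits(grid, "marker_grid"))
  df <- do.call(rbind, lapply(names(grid), function(chr)
    data.frame(chrom = chr, position = format(unclass(grid)[[chr]],
                                              scientific = FALSE, trim = TRUE))))
  write_tsv_plain(df, path)
}

#' Read / write annotated exome variant tables
#'
#' Columns as in [apply_variant_filter()]; empty strings and `NA` in the
#' frequency columns mean "absent from the database".
#'
#' @param path TSV file path.
#' @return Variant data.frame.
#' @export
read_variants_tsv <- function(path) {
  df <- read_tsv_checked(path, c("gene", "region_class", "consequence",
                                 "freq_1000g", "freq_exac",
                                 "in_inhouse_controls", "in_nonhtx_patients",
                                 "n_deleterious_calls"))
  df$freq_1000g <- suppressWarnings(as.numeric(df$freq_1000g))
  df$freq_exac <- suppressWarnings(as.numeric(df$freq_exac))
  df$in_inhouse_controls <- as.logical(df$in_inhouse_controls)
  df$in_nonhtx_patients <- as.logical(df$in_nonhtx_patients)
  df$n_deleterious_calls <- as.integer(df$n_deleterious_calls)
  is_functional(df$consequence)  # vocabulary check; value unused
  df
}

#' @param variants Variant table to write.
#' @rdname read_variants_tsv
#' @export
write_variants_tsv <- function(variants, path) write_tsv_plain(variants, path)

#' Read / write phenotype count tables
#'
#' Long format: `group`, `replicate`, `category`, `count`.
#'
#' @param path TSV file path.
#' @param scheme `"looping"` or `"expression"`.
#' @return Named list of [phenotype_counts()].
#' @export
read_counts_tsv <- function(path, scheme) {
  df <- read_tsv_checked(path, c("group", "replicate", "category", "count"))
  cats <- PHENO_SCHEMES[[match.arg(scheme, names(PHENO_SCHEMES))]]
  lapply(split(df, df$group), function(d) {
    m <- t(vapply(sort(unique(d$replicate)), function(r) {
      row <- d[d$replicate == r, ]
      stats::setNames(row$count[match(cats, row$category)], cats)
    }, numeric(length(cats))))
    phenotype_counts(d$group[1], scheme, m)
  })
}

#' @param counts Named list of [phenotype_counts()] to write.
#' @rdname read_counts_tsv
#' @export
write_counts_tsv <- function(counts, path) {
  df <- do.call(rbind, lapply(counts, function(p) {
    m <- p$counts
    data.frame(group = p$group, replicate = rep(seq_len(nrow(m)), ncol(m)),
               category = rep(colnames(m), each = nrow(m)),
               count = as.vector(m), stringsAsFactors = FALSE)
  }))
  write_tsv_plain(df, path)
}

#' Export calls as BED
#'
#' BED is 0-based half-open; internal coordinates are written as
#' `start - 1`, `end - 1` so that BED length equals the internal length.
#'
#' @param calls Call table.
#' @param path Output path.
#' @export
write_bed <- function(calls, path) {
  validate_cnv_calls(calls)
  lines <- sprintf("%s\t%.0f\t%.0f\t%s_cn%d", calls$chrom, calls$start - 1,
                   calls$end - 1, calls$sample_id, calls$copy_number)
  writeLines(lines, path)
  invisible(path)
}

extdata <- function(name) {
  system.file("extdata", name, package = "htxcnv", mustWork = TRUE)
}

#' Bundled fixture: the 19 published rare CNVs
#'
#' The printed microarray records of the heterotaxy cohort: patient ID,
#' cytoband, hg19 coordinates, impact-type label, printed size (kbp), copy
#' number and altered genes. `impact_class` is the type label mapped onto
#' the classifier vocabulary.
#'
#' @return A call table with extra columns `cytoband`, `type`, `size_kbp`,
#'   `genes_altered`, `impact_class`.
#' @export
htx_table2 <- function() {
  df <- read_cnv_tsv(extdata("table2_cnvs.tsv"))
  df$genes_altered <- df$genes
  df$genes <- NULL
  df$impact_class <- c("Genic del" = "genic_del", "Genic dup" = "genic_dup",
                       "Internal dup" = "internal_dup")[df$type]
  if (anyNA(df$impact_class)) stop("unknown type label in table2 fixture")
  df
}

#' Bundled fixture: cohort phenotype counts
#'
#' Clinical abnormality counts over the 63 recruited patients.
#'
#' @return data.frame with `group`, `category`, `count`.
#' @export
htx_table1 <- function() {
  read_tsv_checked(extdata("table1_cohort.tsv"), c("group", "category", "count"))
}

#' Bundled fixture: curated gene sets
#'
#' Mechanism memberships (cilia, Notch pathway, E3 ubiquitin ligase) for the
#' published candidates, the 14 known heterotaxy genes, and symbol aliases.
#'
#' @return A [curated_gene_sets()] object.
#' @export
htx_gene_sets <- function() {
  mem <- read_tsv_checked(extdata("gene_sets.tsv"), c("symbol", "tag"))
  known <- read_tsv_checked(extdata("known_htx_genes.tsv"), "symbol")$symbol
  aliases <- read_tsv_checked(extdata("gene_aliases.tsv"), c("alias", "symbol"))
  curated_gene_sets(mem, known, aliases)
}
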