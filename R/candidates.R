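# Candidate laterality-gene prioritization.
#
# Genes inside rare CNVs are promoted to candidates when they belong to at
# least one curated mechanism set: ciliary proteome/function, a left-right
# signaling pathway (Notch, Nodal, Hedgehog, Wnt, TGF-beta), or the E3
# ubiquitin-ligase family. The criteria are a union; every matching tag is
# recorded so reports can group candidates by mechanism. A separate screen
# intersects altered genes with the known heterotaxy genes to exclude
# already-explained cases.

#' Normalize gene symbols
#'
#' Upper-cases, strips whitespace, and maps through an optional alias table
#' (two columns: `alias`, `symbol`).
#'
#' @param symbols Character vector.
#' @param aliases Optional alias data.frame.
#' @return Character vector of canonical symbols.
#' @export
normalize_symbol <- function(symbols, aliases = NULL) {
  s <- toupper(gsub("\\s+", "", as.character(symbols)))
  if (!is.null(aliases) && nrow(aliases)) {
    a <- toupper(gsub("\\s+", "", aliases$alias))
    hit <- match(s, a)
    s[!is.na(hit)] <- toupper(gsub("\\s+", "", aliases$symbol))[hit[!is.na(hit)]]
  }
  s
}

#' Construct curated gene sets
#'
#' @param membership data.frame with columns `symbol` and `tag`; tags are
#'   `cilia`, `pathway:<name>` or `e3_ligase`.
#' @param known_htx_genes Character vector of known heterotaxy gene symbols.
#' @param aliases Optional alias data.frame (`alias`, `symbol`).
#' @return List of class `curated_gene_sets`.
#' @export
curated_gene_sets <- function(membership, known_htx_genes = character(0),
                              aliases = NULL) {
  stopifnot(all(c("symbol", "tag") %in% names(membership)))
  ok <- grepl("^(cilia|e3_ligase|pathway:(Notch|Nodal|Hedgehog|Wnt|TGF-b(eta)?))$",
              membership$tag)
  if (!all(ok)) stop("unknown gene-set tag: ",
                     paste(unique(membership$tag[!ok]), collapse = ", "))
  membership$symbol <- normalize_symbol(membership$symbol, aliases)
  structure(list(membership = unique(membership[, c("symbol", "tag")]),
                 known_htx_genes = unique(normalize_symbol(known_htx_genes, aliases)),
                 aliases = aliases),
            class = "curated_gene_sets")
}

split_genes <- function(x) {
  lapply(strsplit(as.character(x), ","), function(g) g[nzchar(trimws(g))])
}

#' Screen altered genes for known heterotaxy genes
#'
#' @param impacts data.frame with columns `sample_id` and `genes_altered`
#'   (comma-joined symbols), e.g. the output of [classify_cnvs()].
#' @param sets A [curated_gene_sets()] object.
#' @return data.frame (`symbol`, `sample_id`, `chrom`, `start`, `end` when
#'   available) with one row per known-gene hit; zero rows when none.
#' @export
screen_known_genes <- function(impacts, sets) {
  stopifnot(inherits(sets, "curated_gene_sets"))
  genes <- split_genes(impacts$genes_altered)
  out <- data.frame(symbol = character(0), sample_id = character(0),
                    stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    hit <- intersect(normalize_symbol(genes[[i]], sets$aliases),
                     sets$known_htx_genes)
    for (h in hit) {
      row <- data.frame(symbol = h, sample_id = impacts$sample_id[i],
                        stringsAsFactors = FALSE)
      for (col in c("chrom", "start", "end")) {
        if (col %in% names(impacts)) row[[col]] <- impacts[[col]][i]
      }
      out <- rbind(out, row)
    }
  }
  out
}

#' Select candidate genes from rare-CNV impacts
#'
#' Every gene altered by a rare CNV that belongs to at least one curated set
#' becomes a candidate; all matching tags are recorded. Output order is
#' deterministic: by patient, then genomic position, then symbol.
#'
#' @param impacts data.frame of rare-CNV impacts with `sample_id`,
#'   `chrom`, `start`, `end`, `genes_altered`.
#' @param sets A [curated_gene_sets()] object.
#' @return data.frame with columns `symbol`, `criteria` (comma-joined tags),
#'   `sample_id`, `chrom`, `start`, `end`.
#' @export
select_candidates <- function(impacts, sets) {
  stopifnot(inherits(sets, "curated_gene_sets"))
  mem <- sets$membership
  genes <- split_genes(impacts$genes_altered)
  rows <- list()
  for (i in seq_along(genes)) {
    syms <- normalize_symbol(genes[[i]], sets$aliases)
    for (s in unique(syms)) {
      tags <- sort(mem$tag[mem$symbol == s])
      if (!length(tags)) next
      rows[[length(rows) + 1L]] <- data.frame(
        symbol = s, criteria = paste(tags, collapse = ","),
        sample_id = as.character(impacts$sample_id[i]),
        chrom = impacts$chrom[i], start = impacts$start[i],
        end = impacts$end[i], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(symbol = character(0), criteria = character(0),
                      sample_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$sample_id, out$chrom, out$start, out$symbol), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
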