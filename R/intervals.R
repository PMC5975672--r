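# Interval algebra on microarray-style genomic segments.
#
# Coordinates are stored as printed by ChAS-style reports (hg19 positions);
# segment length is defined as end - start, i.e. intervals behave as
# half-open [start, end). This convention reproduces printed segment sizes
# exactly and makes marker counting, overlap and union coverage consistent
# with one another.

#' Normalize chromosome labels
#'
#' Strips an optional `chr`/`Chr` prefix and upper-cases sex chromosomes so
#' that `"chr1"`, `"Chr1"` and `"1"` compare equal. Runs at parse time in all
#' readers; downstream code assumes normalized labels.
#'
#' @param chrom Character vector of chromosome labels.
#' @return Character vector of normalized labels (e.g. `"1"`, `"X"`).
#' @export
#' @examples
#' normalize_chrom(c("chr1", "1", "chrX", "x"))
normalize_chrom <- function(chrom) {
  chrom <- trimws(as.character(chrom))
  if (any(!nzchar(chrom)) || anyNA(chrom)) {
    stop("chromosome labels must be non-empty")
  }
  toupper(sub("^[Cc][Hh][Rr]", "", chrom))
}

#' Construct genomic intervals
#'
#' @param chrom Chromosome labels (normalized with [normalize_chrom()]).
#' @param start,end Integer positions (bp), `end >= start`.
#' @return A `data.frame` with columns `chrom`, `start`, `end`.
#' @export
genomic_intervals <- function(chrom, start, end) {
  iv <- data.frame(chrom = normalize_chrom(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   stringsAsFactors = FALSE)
  validate_intervals(iv)
  iv
}

validate_intervals <- function(iv) {
  stopifnot(all(c("chrom", "start", "end") %in% names(iv)))
  if (anyNA(iv$start) || anyNA(iv$end)) stop("interval coordinates must not be NA")
  bad <- which(iv$end < iv$start)
  if (length(bad)) {
    stop(sprintf("malformed interval (end < start) at row %d: %s:%s-%s",
                 bad[1], iv$chrom[bad[1]],
                 format(iv$start[bad[1]], scientific = FALSE),
                 format(iv$end[bad[1]], scientific = FALSE)))
  }
  invisible(iv)
}

#' Segment length in base pairs
#'
#' Length is `end - start` (half-open convention); `length_kb()` divides by
#' 1000 and is reported to 3 decimals elsewhere.
#'
#' @param iv Interval data.frame (`chrom`, `start`, `end`).
#' @return Numeric vector of lengths in bp.
#' @export
#' @examples
#' length_bp(genomic_intervals("1", 145625128, 145927662)) # 302534
length_bp <- function(iv) {
  validate_intervals(iv)
  iv$end - iv$start
}

#' @rdname length_bp
#' @export
length_kb <- function(iv) length_bp(iv) / 1000

#' Pairwise overlap between two intervals
#'
#' Vectorised over rows (recycled). Returns 0 for different chromosomes or
#' disjoint intervals; symmetric in its arguments.
#'
#' @param a,b Interval data.frames.
#' @return Numeric vector of overlap lengths in bp.
#' @export
overlap_bp <- function(a, b) {
  validate_intervals(a); validate_intervals(b)
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n); bi <- rep_len(seq_len(nrow(b)), n)
  ov <- pmin(a$end[ai], b$end[bi]) - pmax(a$start[ai], b$start[bi])
  ov[a$chrom[ai] != b$chrom[bi]] <- 0
  pmax(ov, 0)
}

# Merge intervals on one chromosome into a disjoint sorted union.
merge_union <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- numeric(0); me <- numeric(0)
  for (i in seq_along(start)) {
    if (length(ms) && start[i] <= me[length(me)]) {
      me[length(me)] <- max(me[length(me)], end[i])
    } else {
      ms <- c(ms, start[i]); me <- c(me, end[i])
    }
  }
  list(start = ms, end = me)
}

#' Fraction of a query interval covered by a set of reference intervals
#'
#' Computes the fraction of the query's length covered by the union of the
#' references lying on the same chromosome. Used for the "< 50% overlap with
#' published common CNVs" rarity criterion, where the references are the
#' matching-dosage common-CNV records.
#'
#' @param query A single-row interval data.frame with positive length.
#' @param refs Interval data.frame (0 or more rows).
#' @return A fraction in `[0, 1]`.
#' @export
coverage_fraction <- function(query, refs) {
  validate_intervals(query)
  if (nrow(query) != 1L) stop("query must be a single interval")
  qlen <- query$end - query$start
  if (qlen <= 0) stop("coverage_fraction undefined for zero-length query")
  if (nrow(refs) == 0L) return(0)
  validate_intervals(refs)
  refs <- refs[refs$chrom == query$chrom, , drop = FALSE]
  s <- pmax(refs$start, query$start)
  e <- pmin(refs$end, query$end)
  keep <- e > s
  if (!any(keep)) return(0)
  u <- merge_union(s[keep], e[keep])
  sum(u$end - u$start) / qlen
}

#' Reciprocal overlap between two intervals
#'
#' The standard CNV-equivalence measure: the intersection must cover at least
#' `threshold` of BOTH intervals.
#'
#' @param a,b Single-row interval data.frames.
#' @param threshold Fraction in (0, 1]; default 0.5.
#' @return Logical scalar.
#' @export
reciprocal_overlap <- function(a, b, threshold = 0.5) {
  ov <- overlap_bp(a, b)
  la <- length_bp(a); lb <- length_bp(b)
  la > 0 & lb > 0 & ov / la >= threshold & ov / lb >= threshold
}

#' Marker grids
#'
#' A marker grid is the probe layout of the array: a named list mapping each
#' normalized chromosome label to a strictly increasing numeric vector of
#' probe positions (bp).
#'
#' @param positions Named list of numeric vectors.
#' @return The validated grid (class `marker_grid`).
#' @export
marker_grid <- function(positions) {
  stopifnot(is.list(positions))
  if (length(positions)) {
    if (is.null(names(positions)) || any(!nzchar(names(positions)))) {
      stop("marker grid must be a named list keyed by chromosome")
    }
    names(positions) <- normalize_chrom(names(positions))
    for (chr in names(positions)) {
      p <- positions[[chr]]
      if (is.unsorted(p, strictly = TRUE)) {
        stop(sprintf("marker positions on chromosome %s must be strictly increasing", chr))
      }
    }
  }
  structure(positions, class = "marker_grid")
}

#' Count array markers inside a segment
#'
#' Counts probe positions `p` with `start <= p < end` (half-open, consistent
#' with the length convention). Supports the "at least 25 contiguous markers"
#' rarity criterion when calls carry no marker annotation of their own.
#'
#' @param iv Interval data.frame (any number of rows).
#' @param grid A [marker_grid()].
#' @return Integer vector of marker counts per interval.
#' @export
count_markers <- function(iv, grid) {
  validate_intervals(iv)
  stopifnot(inherits(grid, "marker_grid"))
  vapply(seq_len(nrow(iv)), function(i) {
    p <- grid[[iv$chrom[i]]]
    if (is.null(p)) return(0L)
    # strictly-less-than end: subtract a half-position to exclude p == end
    as.integer(findInterval(iv$end[i] - 0.5, p) - findInterval(iv$start[i] - 0.5, p))
  }, integer(1))
}
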