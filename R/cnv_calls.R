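# CNV call tables: located dosage events with copy number, marker support
# and sample of origin. Calls are plain data.frames with documented columns,
# validated on construction and on file read.

#' Construct a CNV call table
#'
#' A call is a non-diploid dosage event: `copy_number != 2`, with `dosage`
#' derived as `"loss"` (< 2) or `"gain"` (> 2). `n_markers` is the ChAS-style
#' probe-support annotation and may be `NA` when a marker grid will be
#' supplied at filter time.
#'
#' @param chrom,start,end Segment coordinates (see [genomic_intervals()]).
#' @param copy_number Integer copy number per call, `!= 2`.
#' @param sample_id Sample labels.
#' @param n_markers Optional integer marker support (default `NA`).
#' @return A data.frame with columns `chrom`, `start`, `end`, `copy_number`,
#'   `dosage`, `n_markers`, `sample_id`.
#' @export
cnv_calls <- function(chrom, start, end, copy_number, sample_id,
                      n_markers = NA_integer_) {
  n <- length(chrom)
  calls <- data.frame(chrom = if (n) normalize_chrom(chrom) else character(0),
                      start = as.numeric(start), end = as.numeric(end),
                      copy_number = as.integer(copy_number),
                      dosage = rep(NA_character_, n),
                      n_markers = rep_len(suppressWarnings(as.integer(n_markers)), n),
                      sample_id = as.character(sample_id),
                      stringsAsFactors = FALSE)
  calls$dosage <- dosage_of(calls$copy_number)
  validate_cnv_calls(calls)
  calls
}

#' Dosage sign of a copy number
#'
#' @param copy_number Integer vector; values of 2 are invalid (diploid).
#' @return `"loss"` for copy number < 2, `"gain"` for > 2.
#' @export
dosage_of <- function(copy_number) {
  if (anyNA(copy_number) || any(copy_number < 0)) {
    stop("copy_number must be a non-negative integer")
  }
  if (any(copy_number == 2L)) {
    stop("copy_number 2 is diploid, not a CNV call")
  }
  out <- rep(NA_character_, length(copy_number))
  out[copy_number < 2L] <- "loss"
  out[copy_number > 2L] <- "gain"
  out
}

validate_cnv_calls <- function(calls) {
  need <- c("chrom", "start", "end", "copy_number", "dosage", "sample_id")
  miss <- setdiff(need, names(calls))
  if (length(miss)) stop("call table missing columns: ", paste(miss, collapse = ", "))
  validate_intervals(calls)
  if (any(calls$copy_number == 2L)) {
    stop(sprintf("row %d: copy_number 2 is not a CNV",
                 which(calls$copy_number == 2L)[1]))
  }
  expect_dos <- dosage_of(calls$copy_number)
  if (!identical(as.character(calls$dosage), expect_dos)) {
    stop("dosage column inconsistent with copy_number")
  }
  invisible(calls)
}

#' Construct a common-CNV database table
#'
#' Population (DGV-like) CNV records carrying a dosage sign and a carrier
#' frequency; the reference against which patient calls are declared common.
#'
#' @param chrom,start,end Record coordinates.
#' @param dosage `"gain"` or `"loss"` per record.
#' @param frequency Carrier frequency in `[0, 1]`.
#' @return A data.frame with columns `chrom`, `start`, `end`, `dosage`,
#'   `frequency`.
#' @export
common_cnv_db <- function(chrom, start, end, dosage, frequency) {
  db <- data.frame(chrom = normalize_chrom(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   dosage = as.character(dosage),
                   frequency = as.numeric(frequency),
                   stringsAsFactors = FALSE)
  validate_intervals(db)
  if (!all(db$dosage %in% c("gain", "loss"))) {
    stop("dosage must be 'gain' or 'loss'")
  }
  if (anyNA(db$frequency) || any(db$frequency < 0 | db$frequency > 1)) {
    stop("frequency must lie in [0, 1]")
  }
  db
}

empty_common_cnv_db <- function() {
  common_cnv_db(character(0), numeric(0), numeric(0), character(0), numeric(0))
}
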