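# Four-criterion rare-CNV filter.
#
# A microarray call is RARE when it (1) exceeds 50 kb, (2) is supported by at
# least 25 contiguous markers, (3) is not common against the population
# database, and (4) was not seen in any control cohort. Criterion (3) is
# implemented as: a call is common iff >= 50% of its length is covered by the
# union of same-dosage database records whose carrier frequency is >= 1 per
# mille - so a call stays rare if it is low-frequency, low-overlap, or absent
# from the database. Ties at exactly 50% coverage count as common.

#' Rarity filter parameters
#'
#' Defaults encode the published thresholds: segments must be strictly larger
#' than `min_size_kb` (50 kb), carry at least `min_markers` (25) probes, avoid
#' >= `max_common_coverage` (50%) coverage by database records at frequency
#' >= `max_common_frequency` (1 per mille), and be absent from all control
#' cohorts at 50% reciprocal overlap.
#'
#' @param min_size_kb Strict lower size bound in kb.
#' @param min_markers Inclusive minimum marker support.
#' @param max_common_frequency Database records at or above this carrier
#'   frequency count toward commonness.
#' @param max_common_coverage Coverage fraction at or above which a call is
#'   common.
#' @param require_absent_from_controls Apply the control-cohort criterion.
#' @param reciprocal_threshold Reciprocal-overlap fraction used for
#'   control-cohort matching.
#' @return A list of class `rare_filter_params`.
#' @export
rare_filter_params <- function(min_size_kb = 50, min_markers = 25,
                               max_common_frequency = 0.001,
                               max_common_coverage = 0.50,
                               require_absent_from_controls = TRUE,
                               reciprocal_threshold = 0.5) {
  stopifnot(min_size_kb > 0, min_markers > 0,
            max_common_frequency > 0,
            max_common_coverage > 0, max_common_coverage <= 1,
            reciprocal_threshold > 0, reciprocal_threshold <= 1)
  structure(list(min_size_kb = min_size_kb, min_markers = min_markers,
                 max_common_frequency = max_common_frequency,
                 max_common_coverage = max_common_coverage,
                 require_absent_from_controls = isTRUE(require_absent_from_controls),
                 reciprocal_threshold = reciprocal_threshold),
            class = "rare_filter_params")
}

#' Is a call common against the population database?
#'
#' @param call A single-row CNV call table ([cnv_calls()]).
#' @param db Common-CNV database ([common_cnv_db()]).
#' @param params [rare_filter_params()].
#' @return Logical scalar: `TRUE` iff the call is covered at
#'   `>= max_common_coverage` by the union of same-dosage records with
#'   frequency `>= max_common_frequency`.
#' @export
is_common_vs_database <- function(call, db, params = rare_filter_params()) {
  stopifnot(nrow(call) == 1L)
  hits <- db[db$dosage == call$dosage &
               db$frequency >= params$max_common_frequency, , drop = FALSE]
  if (nrow(hits) == 0L) return(FALSE)
  coverage_fraction(call[, c("chrom", "start", "end")],
                    hits[, c("chrom", "start", "end")]) >= params$max_common_coverage
}

#' Was a call observed in a control cohort?
#'
#' A control call matches when it has the same dosage and reciprocal overlap
#' >= `params$reciprocal_threshold` with the query (both directions).
#'
#' @param call A single-row CNV call table.
#' @param cohorts A list of CNV call tables (one per control cohort), or a
#'   single call table.
#' @param params [rare_filter_params()].
#' @return Logical scalar.
#' @export
seen_in_controls <- function(call, cohorts, params = rare_filter_params()) {
  stopifnot(nrow(call) == 1L)
  if (is.data.frame(cohorts)) cohorts <- list(cohorts)
  q <- call[, c("chrom", "start", "end")]
  for (ctrl in cohorts) {
    if (is.null(ctrl) || nrow(ctrl) == 0L) next
    cand <- ctrl[ctrl$dosage == call$dosage & ctrl$chrom == call$chrom, ,
                 drop = FALSE]
    for (j in seq_len(nrow(cand))) {
      if (reciprocal_overlap(q, cand[j, c("chrom", "start", "end")],
                             params$reciprocal_threshold)) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Apply the four-criterion rarity filter
#'
#' Produces one decision per call, in stable input order, with the full set
#' of violated-criterion reason codes (`fails_size`, `fails_markers`,
#' `common_in_database`, `seen_in_controls`). A call is rare iff no reason
#' applies.
#'
#' Marker support is taken from the call's `n_markers` column when present;
#' otherwise it is computed from `grid`. A call with neither is an error.
#'
#' @param calls CNV call table ([cnv_calls()]).
#' @param db Common-CNV database; defaults to empty.
#' @param cohorts List of control-cohort call tables; defaults to none.
#' @param grid Optional [marker_grid()] for calls lacking `n_markers`.
#' @param params [rare_filter_params()].
#' @return The `calls` data.frame with added columns `rare` (logical),
#'   `reasons` (comma-joined codes, `""` when rare) and `markers_used`.
#' @export
apply_rare_filter <- function(calls, db = empty_common_cnv_db(),
                              cohorts = list(), grid = NULL,
                              params = rare_filter_params()) {
  validate_cnv_calls(calls)
  if (is.data.frame(cohorts)) cohorts <- list(cohorts)

  markers <- if ("n_markers" %in% names(calls)) calls$n_markers else
    rep(NA_integer_, nrow(calls))
  need_grid <- is.na(markers)
  if (any(need_grid)) {
    if (is.null(grid)) {
      stop(sprintf("call at row %d has no n_markers and no marker grid was supplied",
                   which(need_grid)[1]))
    }
    markers[need_grid] <- count_markers(
      calls[need_grid, c("chrom", "start", "end"), drop = FALSE], grid)
  }

  n <- nrow(calls)
  rare <- logical(n)
  reasons <- character(n)
  for (i in seq_len(n)) {
    call <- calls[i, , drop = FALSE]
    why <- character(0)
    if (!(length_kb(call) > params$min_size_kb)) why <- c(why, "fails_size")
    if (!(markers[i] >= params$min_markers)) why <- c(why, "fails_markers")
    if (is_common_vs_database(call, db, params)) why <- c(why, "common_in_database")
    if (params$require_absent_from_controls &&
        seen_in_controls(call, cohorts, params)) {
      why <- c(why, "seen_in_controls")
    }
    rare[i] <- length(why) == 0L
    reasons[i] <- paste(why, collapse = ",")
  }
  out <- calls
  out$rare <- rare
  out$reasons <- reasons
  out$markers_used <- as.integer(markers)
  out
}
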