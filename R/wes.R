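# Five-criterion rare-variant filter for candidate-gene mutation screening.
#
# Survivors must (1) lie in an exonic or splicing region, (2) not be
# synonymous, (3) be rarer than 0.1% in both public databases (missing
# frequency counts as rare), (4) be absent from both in-house comparison
# sets, and (5) carry at least one deleterious predictor call. Zygosity is
# carried for reporting but is not a criterion.

FUNCTIONAL_CONSEQUENCES <- c("nonsynonymous", "stopgain", "stoploss",
                             "frameshift_indel", "nonframeshift_indel",
                             "splice_site")
CONSEQUENCE_VOCAB <- c(FUNCTIONAL_CONSEQUENCES, "synonymous")

#' Variant filter parameters
#'
#' @param max_pop_freq Strict upper bound on population frequency in each
#'   public database (default 0.001 = 0.1%).
#' @param min_deleterious_calls Minimum number of predictors calling the
#'   variant deleterious (default 1).
#' @param missing_freq_is_rare Treat a missing database frequency as
#'   satisfying the rarity criterion (default `TRUE`).
#' @return List of class `variant_filter_params`.
#' @export
variant_filter_params <- function(max_pop_freq = 0.001,
                                  min_deleterious_calls = 1L,
                                  missing_freq_is_rare = TRUE) {
  stopifnot(max_pop_freq > 0, max_pop_freq < 1, min_deleterious_calls >= 1)
  structure(list(max_pop_freq = max_pop_freq,
                 min_deleterious_calls = as.integer(min_deleterious_calls),
                 missing_freq_is_rare = isTRUE(missing_freq_is_rare)),
            class = "variant_filter_params")
}

#' Is a variant a functional mutation?
#'
#' Functional mutations are nonsynonymous, stop-gain, stop-loss, frameshift
#' or non-frameshift indels, and splice-site changes.
#'
#' @param consequence Character vector of consequence labels.
#' @return Logical vector.
#' @export
is_functional <- function(consequence) {
  bad <- setdiff(unique(as.character(consequence)), CONSEQUENCE_VOCAB)
  if (length(bad)) {
    stop("unknown consequence label(s): ", paste(bad, collapse = ", "),
         "; accepted: ", paste(CONSEQUENCE_VOCAB, collapse = ", "))
  }
  as.character(consequence) %in% FUNCTIONAL_CONSEQUENCES
}

#' Apply the five-criterion rare-variant filter
#'
#' @param variants data.frame with columns `gene`, `region_class`
#'   (`exonic`/`splicing`/`other`), `consequence` (see [is_functional()]),
#'   `freq_1000g`, `freq_exac` (fractions, `NA` = absent),
#'   `in_inhouse_controls`, `in_nonhtx_patients` (logical),
#'   `n_deleterious_calls` (integer count over non-missing predictor calls).
#'   A `zygosity` column, if present, is passed through untouched.
#' @param params [variant_filter_params()].
#' @return `variants` with added columns `qualifies` (logical) and
#'   `first_failed` (first violated criterion `c1`..`c5`, `""` for
#'   survivors).
#' @export
apply_variant_filter <- function(variants, params = variant_filter_params()) {
  need <- c("gene", "region_class", "consequence", "freq_1000g", "freq_exac",
            "in_inhouse_controls", "in_nonhtx_patients", "n_deleterious_calls")
  miss <- setdiff(need, names(variants))
  if (length(miss)) stop("variant table missing columns: ",
                         paste(miss, collapse = ", "))
  freq_ok <- function(f) {
    if (params$missing_freq_is_rare) is.na(f) | f < params$max_pop_freq
    else !is.na(f) & f < params$max_pop_freq
  }
  c1 <- variants$region_class %in% c("exonic", "splicing")
  c2 <- is_functional(variants$consequence)
  c3 <- freq_ok(variants$freq_1000g) & freq_ok(variants$freq_exac)
  c4 <- !variants$in_inhouse_controls & !variants$in_nonhtx_patients
  c5 <- variants$n_deleterious_calls >= params$min_deleterious_calls
  crit <- cbind(c1, c2, c3, c4, c5)
  qualifies <- rowSums(crit) == 5L
  first_failed <- apply(crit, 1L, function(row) {
    f <- which(!row)
    if (length(f)) paste0("c", f[1]) else ""
  })
  out <- variants
  out$qualifies <- qualifies
  out$first_failed <- first_failed
  out
}
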