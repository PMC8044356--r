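#' Somatic-variant retention rules for heterogeneity scoring
#'
#' Applies the study's retention rules to one sample's annotated calls. A
#' call is kept iff all of the following hold:
#'
#' * `pop_freq_max <= popfreq_max` — common population polymorphisms
#'   (maximum population allele frequency strictly above the cutoff) are
#'   excluded; a missing `pop_freq_max` counts as 0, since absence from the
#'   population databases is evidence the variant is not a polymorphism;
#' * the functional class is protein-altering (see
#'   [protein_altering_effects()]); with `strict_nonsynonymous = TRUE` only
#'   `nonsynonymous_snv` qualifies;
#' * `vaf > vaf_min`, or the call is a cancer hotspot and
#'   `vaf > vaf_min_hotspot` — hotspots are trusted down to a lower allele
#'   fraction.
#'
#' All comparisons are strict in the direction stated: a call at exactly
#' `vaf = vaf_min` (non-hotspot) is excluded, while one at exactly
#' `pop_freq_max = popfreq_max` is retained. The operation is a pure subset
#' selection: order is preserved and it is idempotent.
#'
#' @param calls A `variant_calls` data frame (typically one sample's calls).
#' @param popfreq_max Population-frequency exclusion cutoff (default 0.05).
#' @param vaf_min Minimum VAF for non-hotspot calls (default 0.005, i.e.
#'   0.5%).
#' @param vaf_min_hotspot Minimum VAF for hotspot calls (default 0.001,
#'   i.e. 0.1%).
#' @param strict_nonsynonymous If `TRUE`, restrict the functional-class rule
#'   to `nonsynonymous_snv` only instead of all protein-altering classes.
#' @return The retained subset of `calls`, same columns, original order.
#' @examples
#' calls <- variant_calls(sample_id = "S1", gene = c("TP53", "PIK3CA"),
#'                        chrom = "1", pos = c(100, 200), ref = "A",
#'                        alt = "G", vaf = c(0.3, 0.004),
#'                        pop_freq_max = c(0, 0),
#'                        effect = "nonsynonymous_snv",
#'                        hotspot = c(FALSE, TRUE))
#' nrow(filter_variants(calls))  # both kept: 0.3 > 0.005, hotspot 0.004 > 0.001
#' @export
filter_variants <- function(calls, popfreq_max = 0.05, vaf_min = 0.005,
                            vaf_min_hotspot = 0.001,
                            strict_nonsynonymous = FALSE) {
  validate_variant_calls(calls)
  if (nrow(calls) == 0L) return(calls)
  allowed <- if (strict_nonsynonymous) "nonsynonymous_snv" else {
    protein_altering_effects()
  }
  pfm <- ifelse(is.na(calls$pop_freq_max), 0, calls$pop_freq_max)
  keep <- pfm <= popfreq_max &
    calls$effect %in% allowed &
    (calls$vaf > vaf_min | (calls$hotspot & calls$vaf > vaf_min_hotspot))
  calls[keep, , drop = FALSE]
}

#' Ordered mutant-allele-fraction vector of a sample
#'
#' Extracts the VAFs feeding the MATH statistic, sorted ascending;
#' duplicates are preserved. Accepts a [tumor_sample()] (its variants are
#' used as stored, i.e. already filtered if filtering was applied), a
#' `variant_calls` data frame, or a bare numeric vector.
#'
#' @param x A `tumor_sample`, `variant_calls` data frame, or numeric vector.
#' @return Numeric vector of VAFs, ascending; `numeric(0)` for an empty
#'   sample.
#' @export
vaf_vector <- function(x) {
  vafs <- if (inherits(x, "tumor_sample")) {
    if (is.null(x$variants)) numeric() else x$variants$vaf
  } else if (is.data.frame(x)) {
    x$vaf
  } else {
    as.numeric(x)
  }
  sort(vafs)
}
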