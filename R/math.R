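#' Scaled median absolute deviation
#'
#' The median of the absolute deviations from the sample median, scaled by
#' 1.4826 so that its expectation equals the standard deviation for normal
#' samples. The median is the conventional one (mean of the two middle
#' order statistics for even n). Thin wrapper over [stats::mad()] with the
#' empty-input contract the MATH pipeline needs.
#'
#' @param xs Non-empty numeric vector.
#' @return Non-negative scalar.
#' @examples
#' scaled_mad(c(0.1, 0.2, 0.3, 0.4, 0.5))  # 0.14826
#' @export
scaled_mad <- function(xs) {
  if (length(xs) == 0L) stop("scaled_mad of an empty vector", call. = FALSE)
  if (anyNA(xs)) stop("scaled_mad: NA values in input", call. = FALSE)
  stats::mad(xs, constant = 1.4826)
}

#' Mutant-allele tumor heterogeneity (MATH) score
#'
#' MATH summarises intra-tumor genetic heterogeneity as the percentage ratio
#' of the width to the center of a sample's mutant-allele-fraction
#' distribution:
#'
#' \deqn{\mathrm{MATH} = 100 \cdot \frac{\mathrm{MAD}(x)}{\mathrm{median}(x)}}
#'
#' where MAD is the scaled median absolute deviation ([scaled_mad()]). A
#' wide spread of allele fractions relative to their median indicates many
#' subclonal populations, hence a heterogeneous tumor. The ratio is
#' invariant to rescaling of the input, so fractions and percentages give
#' the same score.
#'
#' Degenerate inputs follow the conventions of the residual-tumor setting:
#' an empty vector (e.g. a pathologic complete response with no retained
#' somatic calls) scores 0 and is flagged empty; a single variant scores 0
#' (no spread); identical non-zero VAFs score 0. A non-empty sample whose
#' median VAF is 0 has no defined center and is an error.
#'
#' @param xs Numeric vector of variant allele fractions in \[0, 1\]
#'   (typically [vaf_vector()] of a filtered sample).
#' @return An object of class `math_score` with fields `value`,
#'   `n_variants`, `median_vaf`, `mad_vaf` and `flagged_empty`.
#' @examples
#' compute_math(c(0.1, 0.2, 0.3, 0.4, 0.5))$value  # 49.42
#' compute_math(0.35)$value                        # 0: single variant
#' compute_math(numeric(0))$flagged_empty          # TRUE, value 0
#' @export
compute_math <- function(xs) {
  xs <- as.numeric(xs)
  if (anyNA(xs)) stop("compute_math: NA values in input", call. = FALSE)
  if (any(xs < 0 | xs > 1)) {
    stop("compute_math: VAFs must lie in [0, 1]", call. = FALSE)
  }
  if (length(xs) == 0L) {
    return(new_math_score(0, 0L, NA_real_, NA_real_, flagged_empty = TRUE))
  }
  med <- stats::median(xs)
  if (med == 0) {
    stop("compute_math: median VAF is 0; MATH is undefined", call. = FALSE)
  }
  mad_x <- scaled_mad(xs)
  new_math_score(100 * mad_x / med, length(xs), med, mad_x,
                 flagged_empty = FALSE)
}

new_math_score <- function(value, n_variants, median_vaf, mad_vaf,
                           flagged_empty) {
  structure(list(value = value, n_variants = as.integer(n_variants),
                 median_vaf = median_vaf, mad_vaf = mad_vaf,
                 flagged_empty = flagged_empty),
            class = "math_score")
}

#' @export
print.math_score <- function(x, ...) {
  if (x$flagged_empty) {
    cat("MATH = 0 (no retained variants)\n")
  } else {
    cat(sprintf("MATH = %.2f  (n = %d, median VAF = %.4f, MAD = %.4f)\n",
                x$value, x$n_variants, x$median_vaf, x$mad_vaf))
  }
  invisible(x)
}

#' Filter a sample's calls and attach its MATH score
#'
#' Convenience pipeline: applies [filter_variants()] to the sample's raw
#' calls, computes [compute_math()] on the retained VAFs, and returns the
#' sample with the score attached. The raw calls are kept as-is; re-run
#' [filter_variants()] to inspect the retained subset.
#'
#' @param sample A [tumor_sample()] carrying raw variant calls.
#' @param ... Passed to [filter_variants()].
#' @return The `tumor_sample` with its `math` field set to a `math_score`.
#' @export
score_sample <- function(sample, ...) {
  stopifnot(inherits(sample, "tumor_sample"))
  if (is.null(sample$variants)) {
    stop("sample carries no variant calls to score", call. = FALSE)
  }
  retained <- filter_variants(sample$variants, ...)
  sample$math <- compute_math(vaf_vector(retained))
  sample
}
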