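#' Tumor sample: one sequenced specimen and its heterogeneity score
#'
#' Bundles a specimen identifier, its timepoint relative to neoadjuvant
#' chemotherapy, its (raw or filtered) variant calls and, once computed, its
#' MATH score. Fixture records built from published summary tables carry a
#' bare numeric `math` and no variants; [score_sample()] fills in a full
#' [math_score] from the calls.
#'
#' @param sample_id Specimen identifier.
#' @param timepoint `"pre_nac"` or `"post_nac"`.
#' @param variants Optional `variant_calls` data frame for the sample.
#' @param math Optional MATH value: a `math_score` object or a bare
#'   non-negative number.
#' @return An object of class `tumor_sample`.
#' @export
tumor_sample <- function(sample_id, timepoint = c("pre_nac", "post_nac"),
                         variants = NULL, math = NULL) {
  timepoint <- match.arg(timepoint)
  if (!is.null(variants)) {
    validate_variant_calls(variants)
    if (nrow(variants) > 0L && !all(variants$sample_id == sample_id)) {
      stop("variants carry sample_id(s) other than ", dQuote(sample_id),
           call. = FALSE)
    }
  }
  if (!is.null(math) && math_value(math) < 0) {
    stop("math must be non-negative", call. = FALSE)
  }
  structure(list(sample_id = sample_id, timepoint = timepoint,
                 variants = variants, math = math),
            class = "tumor_sample")
}

#' Extract the numeric MATH value from a score or a bare number
#'
#' @param x A `math_score`, a number, or `NULL` (returns `NA`).
#' @return A single numeric value.
#' @export
math_value <- function(x) {
  if (is.null(x)) return(NA_real_)
  if (inherits(x, "math_score")) return(x$value)
  as.numeric(x)
}

#' @export
print.tumor_sample <- function(x, ...) {
  cat("<tumor_sample>", x$sample_id, sprintf("[%s]", x$timepoint),
      if (!is.null(x$variants)) sprintf("%d calls", nrow(x$variants)),
      if (!is.null(x$math)) sprintf("MATH = %.2f", math_value(x$math)),
      "\n")
  invisible(x)
}

#' Patient record: paired pre/post-NAC samples with clinical annotation
#'
#' @param pre,post [tumor_sample()] objects for the pre-NAC biopsy and the
#'   post-NAC residual tumor.
#' @param subtype Molecular subtype, one of `"luminal_A"`, `"luminal_B"`,
#'   `"luminal_B_her2_pos"`, `"her2_pos"`, `"triple_negative"`.
#' @param d_pre_cm Longest tumor diameter before NAC in cm (MRI), `NA` if
#'   unknown; must be positive when present.
#' @param d_post_cm Longest residual diameter in cm (pathology), `NA` if
#'   unknown; must be non-negative when present.
#' @param mode Shrinkage mode, `"CSM"` or `"NCSM"`. When both diameters are
#'   present the label must agree with [classify_shrinkage()].
#' @param submode Optional morphological submode, one of `"pcr"`,
#'   `"isolated"`, `"nodular"`, `"clumps_scattered"`, `"diffuse"`.
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(pre, post, subtype, d_pre_cm = NA_real_,
                           d_post_cm = NA_real_, mode = NULL,
                           submode = NULL) {
  stopifnot(inherits(pre, "tumor_sample"), inherits(post, "tumor_sample"))
  if (pre$timepoint != "pre_nac" || post$timepoint != "post_nac") {
    stop("pre/post samples must carry timepoints pre_nac and post_nac",
         call. = FALSE)
  }
  if (!subtype %in% subtype_levels()) {
    stop("unknown subtype ", dQuote(subtype), call. = FALSE)
  }
  if (!is.na(d_pre_cm) && d_pre_cm <= 0) {
    stop("d_pre_cm must be > 0", call. = FALSE)
  }
  if (!is.na(d_post_cm) && d_post_cm < 0) {
    stop("d_post_cm must be >= 0", call. = FALSE)
  }
  if (!is.null(mode)) {
    if (!mode %in% mode_levels()) {
      stop("mode must be 'CSM' or 'NCSM'", call. = FALSE)
    }
    if (!is.na(d_pre_cm) && !is.na(d_post_cm)) {
      implied <- classify_shrinkage(d_pre_cm, d_post_cm)$mode
      if (implied != mode) {
        stop("mode ", dQuote(mode), " contradicts the diameters, which ",
             "imply ", dQuote(implied), call. = FALSE)
      }
    }
  }
  if (!is.null(submode) && is.na(submode)) submode <- NULL
  if (!is.null(submode) && !submode %in% submode_levels()) {
    stop("unknown submode ", dQuote(submode), call. = FALSE)
  }
  structure(list(pre = pre, post = post, subtype = subtype,
                 d_pre_cm = d_pre_cm, d_post_cm = d_post_cm,
                 mode = mode, submode = submode),
            class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record> %s/%s  %s  mode=%s  MATH %.2f -> %.2f\n",
              x$pre$sample_id, x$post$sample_id, x$subtype,
              if (is.null(x$mode)) "?" else x$mode,
              math_value(x$pre$math), math_value(x$post$math)))
  invisible(x)
}

#' Pool per-sample MATH values and shrinkage-mode labels from a cohort
#'
#' The unit of the ROC analysis: by default every sequenced sample (pre and
#' post) enters separately, labeled with its patient's shrinkage mode, so a
#' cohort of n patients yields 2n score/label pairs. Per-patient
#' aggregations of the pre/post pair are available as alternatives.
#'
#' @param records List of [patient_record()] objects.
#' @param unit `"pooled"` (default), or one of `"patient_min"`,
#'   `"patient_max"`, `"pre_only"`, `"post_only"` which yield one value per
#'   patient.
#' @return A data frame with columns `sample_id`, `score` (MATH) and `label`
#'   (`"CSM"`/`"NCSM"`).
#' @export
pooled_math <- function(records, unit = c("pooled", "patient_min",
                                          "patient_max", "pre_only",
                                          "post_only")) {
  unit <- match.arg(unit)
  stopifnot(length(records) > 0L)
  rows <- lapply(records, function(r) {
    pre <- math_value(r$pre$math)
    post <- math_value(r$post$math)
    switch(unit,
      pooled = data.frame(
        sample_id = c(r$pre$sample_id, r$post$sample_id),
        score = c(pre, post), label = r$mode,
        stringsAsFactors = FALSE),
      patient_min = data.frame(sample_id = r$pre$sample_id,
                               score = min(pre, post), label = r$mode,
                               stringsAsFactors = FALSE),
      patient_max = data.frame(sample_id = r$pre$sample_id,
                               score = max(pre, post), label = r$mode,
                               stringsAsFactors = FALSE),
      pre_only = data.frame(sample_id = r$pre$sample_id, score = pre,
                            label = r$mode, stringsAsFactors = FALSE),
      post_only = data.frame(sample_id = r$post$sample_id, score = post,
                             label = r$mode, stringsAsFactors = FALSE)
    )
  })
  do.call(rbind, rows)
}
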