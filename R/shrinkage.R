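#' Longest-diameter retraction rate after neoadjuvant chemotherapy
#'
#' Percent reduction of the longest tumor diameter, comparing the residual
#' tumor (pathology) with the primary tumor before NAC (MRI). Negative when
#' the tumor grew. Both inputs are treated as plain lengths in cm; the
#' differing measurement modalities are accepted as given.
#'
#' @param d_pre_cm Longest diameter before NAC, cm; must be > 0.
#' @param d_post_cm Longest residual diameter, cm; must be >= 0.
#' @return Retraction rate in percent: `100 * (d_pre - d_post) / d_pre`.
#' @examples
#' retraction_rate(5, 2)  # 60
#' @export
retraction_rate <- function(d_pre_cm, d_post_cm) {
  if (any(d_pre_cm <= 0)) stop("d_pre_cm must be > 0", call. = FALSE)
  if (any(d_post_cm < 0)) stop("d_post_cm must be >= 0", call. = FALSE)
  100 * (d_pre_cm - d_post_cm) / d_pre_cm
}

#' Classify the pathological shrinkage mode after NAC
#'
#' The size rule is decisive: concentric shrinkage mode (CSM) iff the
#' residual longest diameter is at most 2 cm *and* the retraction rate is
#' at least 50%; otherwise non-concentric (NCSM, residual > 2 cm and/or
#' retraction < 50%). Both boundaries are inclusive for CSM: a residual of
#' exactly 2.0 cm with exactly 50% retraction is CSM.
#'
#' Morphology flags refine the call into a submode but never change the
#' CSM/NCSM decision itself: a residual diameter of 0 is a pathologic
#' complete response (`"pcr"`); `multinodular` maps to `"nodular"`;
#' `diffuse` to `"diffuse"`; `surrounding_lesions` to `"clumps_scattered"`
#' under CSM size criteria and `"isolated"` under NCSM criteria; flags all
#' absent or all `FALSE` give `"isolated"` (`NA` submode when no flag was
#' supplied at all and the tumor is not a pCR).
#'
#' @param d_pre_cm,d_post_cm Longest diameters in cm (see
#'   [retraction_rate()]).
#' @param surrounding_lesions,multinodular,diffuse Optional logical
#'   morphology flags from the pathological reconstruction.
#' @return A list with elements `mode` (`"CSM"`/`"NCSM"`), `submode`
#'   (character or `NA`) and `retraction_pct`.
#' @examples
#' classify_shrinkage(5, 0)    # CSM, pcr
#' classify_shrinkage(5, 2)    # CSM: 60% >= 50 and 2 <= 2
#' classify_shrinkage(1.8, 1)  # NCSM: retraction 44.4% < 50
#' @export
classify_shrinkage <- function(d_pre_cm, d_post_cm,
                               surrounding_lesions = NA,
                               multinodular = NA, diffuse = NA) {
  rate <- retraction_rate(d_pre_cm, d_post_cm)
  csm <- d_post_cm <= 2 & rate >= 50
  mode <- if (csm) "CSM" else "NCSM"
  flags_given <- !all(is.na(c(surrounding_lesions, multinodular, diffuse)))
  submode <- if (d_post_cm == 0) {
    "pcr"
  } else if (isTRUE(multinodular)) {
    "nodular"
  } else if (isTRUE(diffuse)) {
    "diffuse"
  } else if (isTRUE(surrounding_lesions)) {
    if (csm) "clumps_scattered" else "isolated"
  } else if (flags_given) {
    "isolated"
  } else {
    NA_character_
  }
  list(mode = mode, submode = submode, retraction_pct = rate)
}

#' Assign the molecular subtype from an immunohistochemistry profile
#'
#' Standard IHC decision rules: hormone-receptor positive iff ER or PR
#' expression is at least 1%; HER2 positive iff IHC grade 3, or grade 2
#' with gene amplification confirmed by FISH (a grade-2 result without a
#' FISH result is an error); Ki-67 high iff strictly above 20%. The
#' HR/HER2/Ki-67 combination maps onto the five working subtypes, the
#' luminal A vs B split being made on Ki-67 alone.
#'
#' @param er_percent,pr_percent Estrogen/progesterone receptor expression
#'   rates in \[0, 100\].
#' @param her2_ihc HER2 IHC grade: 0, 1, 2 or 3.
#' @param fish_amplified Logical FISH amplification result; required when
#'   `her2_ihc == 2`, ignored otherwise.
#' @param ki67_percent Ki-67 proliferation index in \[0, 100\].
#' @return One of `"luminal_A"`, `"luminal_B"`, `"luminal_B_her2_pos"`,
#'   `"her2_pos"`, `"triple_negative"`.
#' @examples
#' assign_subtype(0, 0, her2_ihc = 3, ki67_percent = 30)   # her2_pos
#' assign_subtype(5, 0, her2_ihc = 0, ki67_percent = 10)   # luminal_A
#' @export
assign_subtype <- function(er_percent, pr_percent, her2_ihc,
                           fish_amplified = NA, ki67_percent) {
  stopifnot(er_percent >= 0, er_percent <= 100,
            pr_percent >= 0, pr_percent <= 100,
            ki67_percent >= 0, ki67_percent <= 100,
            her2_ihc %in% 0:3)
  hr_pos <- er_percent >= 1 || pr_percent >= 1
  her2_pos <- if (her2_ihc == 3) {
    TRUE
  } else if (her2_ihc == 2) {
    if (is.na(fish_amplified)) {
      stop("HER2 IHC grade 2 requires a FISH result", call. = FALSE)
    }
    isTRUE(fish_amplified)
  } else {
    FALSE
  }
  ki67_high <- ki67_percent > 20
  if (!hr_pos && !her2_pos) return("triple_negative")
  if (!hr_pos && her2_pos) return("her2_pos")
  if (hr_pos && her2_pos) return("luminal_B_her2_pos")
  if (ki67_high) "luminal_B" else "luminal_A"
}
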