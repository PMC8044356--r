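#' Published 17-patient breast-cancer NAC cohort
#'
#' The per-patient summary of the study cohort: 17 patients with paired
#' pre-/post-NAC targeted-panel sequencing, each with the MATH value of both
#' specimens, the molecular subtype and the pathological shrinkage mode
#' (13 concentric, 4 non-concentric). Tumor diameters were not published and
#' are `NA`. These records drive the desk-scale cohort statistics: pooled
#' ROC/AUC, threshold analysis and group summaries.
#'
#' @return A list of 17 [patient_record()] objects.
#' @examples
#' cohort <- table1_fixture()
#' length(cohort)                      # 17
#' sum(vapply(cohort, function(r) r$mode == "CSM", logical(1)))  # 13
#' @export
table1_fixture <- function() {
  tab <- data.frame(
    pre_id = c("C1803725", "C1803704", "C1803878", "C1803804", "C1803790",
               "C1803787", "C1803814", "C1803796", "C1803799", "C1803870",
               "C1803783", "C1803813", "C1803792", "C1803817", "C1803805",
               "C1803791", "C1803876"),
    post_id = c("C1803700", "C1803772", "C1803788", "C1803818", "C1803821",
                "C1803826", "C1803829", "C1803830", "C1803833", "C1803834",
                "C1803840", "C1803841", "C1803854", "C1803862", "C1803863",
                "C1803869", "C1803873"),
    pre_math = c(16.41, 79.74, 27.4, 92.47, 59.7, 70.21, 93.11, 24.36,
                 21.42, 48.5, 136.3, 57.84, 36.1, 0, 42.74, 79.36, 9.8),
    post_math = c(1.1, 128, 93.22, 15.3, 102.7, 115.7, 0, 71, 85.32, 66.29,
                  130.1, 39.66, 24.68, 0, 47.38, 46.86, 121.55),
    subtype = c("luminal_B_her2_pos", "luminal_B", "triple_negative",
                "luminal_B", "luminal_A", "her2_pos", "triple_negative",
                "luminal_A", "luminal_A", "luminal_B_her2_pos", "luminal_B",
                "luminal_B_her2_pos", "luminal_B_her2_pos", "her2_pos",
                "her2_pos", "luminal_A", "her2_pos"),
    mode = c("CSM", "NCSM", "CSM", "CSM", "NCSM", "NCSM", "CSM", "CSM",
             "CSM", "CSM", "NCSM", "CSM", "CSM", "CSM", "CSM", "CSM",
             "CSM"),
    stringsAsFactors = FALSE
  )
  lapply(seq_len(nrow(tab)), function(i) {
    patient_record(
      pre = tumor_sample(tab$pre_id[i], "pre_nac", math = tab$pre_math[i]),
      post = tumor_sample(tab$post_id[i], "post_nac",
                          math = tab$post_math[i]),
      subtype = tab$subtype[i], mode = tab$mode[i]
    )
  })
}

#' Published hot-mutation contingency tables
#'
#' The 2x2 counts comparing TP53 and PIK3CA hot-mutation carriers between
#' the concentric (n = 13) and non-concentric (n = 4) shrinkage-mode groups,
#' separately before and after NAC. Rows are the mode groups (CSM first),
#' columns are mutated / not mutated.
#'
#' @return A named list of four [contingency_table()] objects:
#'   `tp53_pre`, `tp53_post`, `pik3ca_pre`, `pik3ca_post`.
#' @examples
#' fisher_exact_two_sided(table2_fixture()$tp53_post)  # 0.029
#' @export
table2_fixture <- function() {
  list(
    tp53_pre = contingency_table(9, 4, 2, 2),
    tp53_post = contingency_table(4, 9, 4, 0),
    pik3ca_pre = contingency_table(3, 10, 2, 2),
    pik3ca_post = contingency_table(5, 8, 3, 1)
  )
}
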