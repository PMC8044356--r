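#' Write a cohort to per-patient and contingency report files
#'
#' Emits a per-patient summary table (`patients.tsv`: sample identifiers,
#' MATH values, subtype, diameters, mode, submode) and, when the records
#' carry variant calls, a gene-frequency summary (`gene_frequency.tsv`:
#' per-gene, per-timepoint carrier counts by shrinkage-mode group with the
#' two-sided Fisher exact p-value). The per-patient table round-trips
#' losslessly through [read_cohort_report()].
#'
#' @param records Non-empty list of [patient_record()] objects.
#' @param path Output directory; created if needed.
#' @return Character vector of the files written, invisibly.
#' @export
write_cohort_report <- function(records, path) {
  if (length(records) == 0L) stop("no records to report", call. = FALSE)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  per_patient <- do.call(rbind, lapply(records, function(r) {
    data.frame(
      pre_sample = r$pre$sample_id, post_sample = r$post$sample_id,
      pre_math = math_value(r$pre$math), post_math = math_value(r$post$math),
      subtype = r$subtype, d_pre_cm = r$d_pre_cm, d_post_cm = r$d_post_cm,
      mode = if (is.null(r$mode)) NA_character_ else r$mode,
      submode = if (is.null(r$submode)) NA_character_ else r$submode,
      stringsAsFactors = FALSE
    )
  }))
  patients_path <- file.path(path, "patients.tsv")
  write.table(per_patient, patients_path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  written <- patients_path

  with_variants <- all(vapply(records, function(r) {
    !is.null(r$pre$variants) && !is.null(r$post$variants)
  }, logical(1)))
  if (with_variants) {
    genes <- sort(unique(unlist(lapply(records, function(r) {
      c(r$pre$variants$gene, r$post$variants$gene)
    }))))
    rows <- list()
    for (g in genes) {
      for (tp in timepoint_levels()) {
        ct <- mutation_frequency_table(records, g, timepoint = tp,
                                       genes = genes)
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, timepoint = tp,
          csm_mutated = ct[1, 1], csm_not = ct[1, 2],
          ncsm_mutated = ct[2, 1], ncsm_not = ct[2, 2],
          p_fisher = fisher_exact_two_sided(ct),
          stringsAsFactors = FALSE
        )
      }
    }
    freq_path <- file.path(path, "gene_frequency.tsv")
    write.table(do.call(rbind, rows), freq_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    written <- c(written, freq_path)
  }
  invisible(written)
}

#' Read a per-patient report back into patient records
#'
#' Inverse of the per-patient table written by [write_cohort_report()].
#' Variant calls are not part of the report and come back `NULL`; all other
#' fields round-trip exactly.
#'
#' @param path The directory given to [write_cohort_report()].
#' @return A list of [patient_record()] objects.
#' @export
read_cohort_report <- function(path) {
  patients_path <- file.path(path, "patients.tsv")
  if (!file.exists(patients_path)) {
    stop("no patients.tsv under ", path, call. = FALSE)
  }
  tab <- read.delim(patients_path, stringsAsFactors = FALSE,
                    na.strings = "NA")
  lapply(seq_len(nrow(tab)), function(i) {
    patient_record(
      pre = tumor_sample(tab$pre_sample[i], "pre_nac",
                         math = tab$pre_math[i]),
      post = tumor_sample(tab$post_sample[i], "post_nac",
                          math = tab$post_math[i]),
      subtype = tab$subtype[i],
      d_pre_cm = tab$d_pre_cm[i], d_post_cm = tab$d_post_cm[i],
      mode = if (is.na(tab$mode[i])) NULL else tab$mode[i],
      submode = if (is.na(tab$submode[i])) NULL else tab$submode[i]
    )
  })
}
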