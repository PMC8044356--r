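#' 2x2 contingency table of mutation carriers by group
#'
#' Rows are the two pre-defined groups (conventionally CSM then NCSM),
#' columns are mutated / not mutated.
#'
#' @param a,b Counts for group 1: mutated, not mutated.
#' @param c,d Counts for group 2: mutated, not mutated.
#' @return A 2x2 integer matrix of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("contingency counts must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) == 0) stop("contingency table is all zero", call. = FALSE)
  m <- matrix(as.integer(counts), nrow = 2, byrow = TRUE,
              dimnames = list(group = c("group1", "group2"),
                              status = c("mutated", "not_mutated")))
  class(m) <- c("contingency_table", class(m))
  m
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' The conditional exact test: with all margins fixed, the two-sided
#' p-value is the sum of hypergeometric probabilities of every table whose
#' probability does not exceed that of the observed one (the convention
#' used by [stats::fisher.test()], to which this delegates).
#'
#' @param t A [contingency_table()] or any 2x2 count matrix.
#' @return The two-sided p-value in (0, 1].
#' @examples
#' fisher_exact_two_sided(contingency_table(4, 9, 4, 0))  # 0.029
#' @export
fisher_exact_two_sided <- function(t) {
  t <- unclass(t)
  stopifnot(is.matrix(t), all(dim(t) == c(2L, 2L)))
  if (any(t < 0)) stop("negative counts", call. = FALSE)
  stats::fisher.test(t, alternative = "two.sided")$p.value
}

check_scores_labels <- function(scores, labels, positive, negative) {
  stopifnot(length(scores) == length(labels), length(scores) > 0L)
  if (anyNA(scores) || anyNA(labels)) stop("NA in scores or labels",
                                           call. = FALSE)
  unknown <- setdiff(unique(labels), c(positive, negative))
  if (length(unknown) > 0L) {
    stop("labels other than ", dQuote(positive), "/", dQuote(negative),
         ": ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!any(labels == positive) || !any(labels == negative)) {
    stop("need at least one ", dQuote(positive), " and one ",
         dQuote(negative), " sample", call. = FALSE)
  }
}

#' ROC analysis of a heterogeneity score against shrinkage mode
#'
#' The AUC is the pair-counting (Mann-Whitney) probability that a
#' positive-class sample scores above a negative-class sample, with half
#' credit for ties: `[#(pos > neg) + 0.5 * #(pos == neg)] / (n_pos * n_neg)`.
#' The positive class is the one expected to score high — NCSM for MATH.
#' Operating points are evaluated at every threshold interval between
#' distinct observed scores under the decision rule of
#' [confusion_at_threshold()], and the Youden-optimal threshold interval is
#' attached (see [youden_threshold()]).
#'
#' @param scores Numeric scores (MATH values).
#' @param labels Class labels, two levels.
#' @param positive The label of the high-scoring class (default `"NCSM"`).
#' @param negative The label of the low-scoring class (default `"CSM"`).
#' @return An object of class `roc_result`: fields `scores`, `labels`,
#'   `auc`, `points` (data frame `threshold`, `sensitivity`,
#'   `specificity`), `optimal_interval`.
#' @examples
#' dat <- pooled_math(table1_fixture())
#' roc_auc(dat$score, dat$label)$auc  # 0.894
#' @export
roc_auc <- function(scores, labels, positive = "NCSM", negative = "CSM") {
  check_scores_labels(scores, labels, positive, negative)
  pos <- scores[labels == positive]
  neg <- scores[labels == negative]
  ## pair counting via the rank-sum identity; O(n log n)
  r <- rank(c(pos, neg), ties.method = "average")
  auc <- (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
  thresholds <- threshold_grid(scores)
  points <- data.frame(
    threshold = thresholds,
    t(vapply(thresholds, function(th) {
      unlist(confusion_at_threshold(scores, labels, th,
                                    positive = positive,
                                    negative = negative))
    }, c(sensitivity = 0, specificity = 0)))
  )
  structure(list(scores = scores, labels = labels, positive = positive,
                 negative = negative, auc = auc, points = points,
                 optimal_interval = youden_threshold(scores, labels,
                                                     positive = positive,
                                                     negative = negative)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  oi <- x$optimal_interval
  cat(sprintf("ROC: AUC = %.3f over %d samples (%d positive)\n",
              x$auc, length(x$scores), sum(x$labels == x$positive)))
  cat(sprintf("Youden-optimal threshold interval: (%.4g, %.4g], J = %.3f\n",
              oi$low, oi$high, oi$j))
  invisible(x)
}

## One representative threshold per constant piece of the decision rule:
## predictions are constant for t in (s_i, s_{i+1}], so probe each interval,
## plus one point below all scores and one above.
threshold_grid <- function(scores) {
  s <- sort(unique(scores))
  c(s[1] - 1, (head(s, -1) + tail(s, -1)) / 2, s[length(s)] + 1)
}

#' Sensitivity and specificity of the threshold decision rule
#'
#' The decision rule of the threshold analysis: predict the low-score class
#' (CSM) when `score < threshold`, strictly, and the high-score class
#' otherwise. Following the clinical framing — a low heterogeneity score
#' flags a patient as a concentric-shrinkage candidate — sensitivity is the
#' fraction of CSM-labeled samples predicted CSM, and specificity the
#' fraction of NCSM-labeled samples predicted NCSM.
#'
#' @inheritParams roc_auc
#' @param threshold Decision threshold on the score.
#' @return List with `sensitivity` and `specificity`, both in \[0, 1\].
#' @examples
#' dat <- pooled_math(table1_fixture())
#' confusion_at_threshold(dat$score, dat$label, 58)  # 0.692, 1.0
#' @export
confusion_at_threshold <- function(scores, labels, threshold,
                                   positive = "NCSM", negative = "CSM") {
  check_scores_labels(scores, labels, positive, negative)
  neg_scores <- scores[labels == negative]
  pos_scores <- scores[labels == positive]
  list(sensitivity = mean(neg_scores < threshold),
       specificity = mean(pos_scores >= threshold))
}

#' Youden-optimal threshold interval
#'
#' Sweeps every constant piece of the strict `score < threshold` rule —
#' the decision is unchanged for thresholds within `(s_i, s_(i+1)]` between
#' adjacent distinct scores — and returns the half-open interval of
#' thresholds maximizing the Youden index J = sensitivity + specificity - 1.
#' Adjacent maximal pieces are merged; if several separated pieces tie, the
#' lowest is returned. The interval always brackets at least one midpoint
#' between observed scores.
#'
#' @inheritParams roc_auc
#' @return List with `low`, `high` (the interval `(low, high]`, possibly
#'   infinite at either end) and `j`, the maximal Youden index.
#' @examples
#' dat <- pooled_math(table1_fixture())
#' youden_threshold(dat$score, dat$label)  # (57.84, 59.7], contains 58
#' @export
youden_threshold <- function(scores, labels, positive = "NCSM",
                             negative = "CSM") {
  check_scores_labels(scores, labels, positive, negative)
  s <- sort(unique(scores))
  ## pieces: (-Inf, s1], (s1, s2], ..., (s_{n-1}, s_n], (s_n, Inf)
  lows <- c(-Inf, s)
  highs <- c(s, Inf)
  probe <- ifelse(is.finite(highs), highs,
                  s[length(s)] + 1)  # any point inside the last piece
  j <- vapply(probe, function(th) {
    cm <- confusion_at_threshold(scores, labels, th, positive = positive,
                                 negative = negative)
    cm$sensitivity + cm$specificity - 1
  }, 0)
  jmax <- max(j)
  best <- which(j >= jmax - 1e-12)
  ## merge the first run of adjacent maximal pieces
  run_end <- best[1]
  while (run_end + 1L <= length(j) && (run_end + 1L) %in% best) {
    run_end <- run_end + 1L
  }
  list(low = lows[best[1]], high = highs[run_end], j = jmax)
}

#' Group summaries: mean and lower median
#'
#' `group_mean()` is the arithmetic mean. `group_lower_median()` is the
#' lower-median convention: the `ceiling(n/2)`-th order statistic, i.e. for
#' even n the lower of the two middle values — the convention under which
#' the published group medians of pooled MATH values are reproduced exactly
#' by observed sample values. The conventional mid-mean median remains
#' available as [stats::median()].
#'
#' @param values Non-empty numeric vector.
#' @return A single number.
#' @examples
#' group_lower_median(c(1, 2, 3, 4))  # 2
#' @export
group_mean <- function(values) {
  if (length(values) == 0L) stop("empty input", call. = FALSE)
  mean(values)
}

#' @rdname group_mean
#' @export
group_lower_median <- function(values) {
  if (length(values) == 0L) stop("empty input", call. = FALSE)
  sort(values)[ceiling(length(values) / 2)]
}

#' Rank-based comparison of MATH between shrinkage-mode groups
#'
#' Compares the pooled per-sample MATH values of the CSM and NCSM groups
#' with the Wilcoxon rank-sum test. Note this is a deliberate
#' methodological substitution: group comparisons of a continuous
#' heterogeneity score are sometimes attributed to the Fisher exact test
#' in the clinical literature, but that test is defined for contingency
#' counts only; the rank-sum test is the standard nonparametric choice for
#' this comparison.
#'
#' @param records List of [patient_record()] objects with MATH values.
#' @param unit Sample pooling passed to [pooled_math()].
#' @return List with `p_value`, the per-group lower medians
#'   (`median_csm`, `median_ncsm`) and group sizes.
#' @export
math_group_test <- function(records, unit = "pooled") {
  dat <- pooled_math(records, unit = unit)
  csm <- dat$score[dat$label == "CSM"]
  ncsm <- dat$score[dat$label == "NCSM"]
  if (length(csm) == 0L || length(ncsm) == 0L) {
    stop("both shrinkage-mode groups must be non-empty", call. = FALSE)
  }
  wt <- suppressWarnings(stats::wilcox.test(csm, ncsm))
  list(p_value = wt$p.value,
       median_csm = group_lower_median(csm),
       median_ncsm = group_lower_median(ncsm),
       n_csm = length(csm), n_ncsm = length(ncsm))
}

#' Partition mutated gene sets by timepoint
#'
#' Splits the union of genes mutated before and after NAC into the genes
#' lost under therapy (pre-only), those persisting (shared), and those
#' emerging (post-only). The three sets are disjoint and cover the union.
#'
#' @param pre_genes,post_genes Character vectors (treated as sets).
#' @return List with `pre_only`, `shared`, `post_only`, each sorted.
#' @examples
#' partition_gene_sets(c("TP53", "PIK3CA"), c("PIK3CA", "BRCA2"))
#' @export
partition_gene_sets <- function(pre_genes, post_genes) {
  pre_genes <- unique(as.character(pre_genes))
  post_genes <- unique(as.character(post_genes))
  list(pre_only = sort(setdiff(pre_genes, post_genes)),
       shared = sort(intersect(pre_genes, post_genes)),
       post_only = sort(setdiff(post_genes, pre_genes)))
}

#' Mutation-carrier contingency table for one gene and timepoint
#'
#' Counts, separately in the CSM and NCSM groups, the patients whose sample
#' at the requested timepoint carries at least one retained call in `gene`,
#' yielding the 2x2 table that [fisher_exact_two_sided()] consumes. The
#' gene must belong to the cohort's observed gene universe (or to `genes`
#' when supplied); a known gene with no carriers at that timepoint gives a
#' zero mutated column.
#'
#' @param records List of [patient_record()] objects whose samples carry
#'   variant calls.
#' @param gene Gene symbol.
#' @param timepoint `"pre_nac"` or `"post_nac"`.
#' @param genes Optional character vector defining the admissible gene
#'   universe; defaults to all genes seen in the cohort at any timepoint.
#' @return A [contingency_table()] with rows CSM, NCSM.
#' @export
mutation_frequency_table <- function(records, gene,
                                     timepoint = c("pre_nac", "post_nac"),
                                     genes = NULL) {
  timepoint <- match.arg(timepoint)
  stopifnot(length(records) > 0L)
  sample_genes <- function(smp) {
    if (is.null(smp$variants)) character() else unique(smp$variants$gene)
  }
  if (is.null(genes)) {
    genes <- unique(unlist(lapply(records, function(r) {
      c(sample_genes(r$pre), sample_genes(r$post))
    })))
  }
  if (!gene %in% genes) stop("unknown gene: ", gene, call. = FALSE)
  mutated <- vapply(records, function(r) {
    smp <- if (timepoint == "pre_nac") r$pre else r$post
    gene %in% sample_genes(smp)
  }, logical(1))
  mode <- vapply(records, function(r) r$mode, character(1))
  contingency_table(sum(mutated & mode == "CSM"),
                    sum(!mutated & mode == "CSM"),
                    sum(mutated & mode == "NCSM"),
                    sum(!mutated & mode == "NCSM"))
}
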