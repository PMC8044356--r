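test_that("Fisher exact p-values match the published contingency tables", {
  t2 <- table2_fixture()
  expect_equal(round(fisher_exact_two_sided(t2$tp53_post), 3), 0.029)
  expect_equal(round(fisher_exact_two_sided(t2$tp53_pre), 3), 0.584)
  expect_equal(round(fisher_exact_two_sided(t2$pik3ca_pre), 3), 0.538)
  expect_equal(round(fisher_exact_two_sided(t2$pik3ca_post), 3), 0.294)
  expect_equal(fisher_exact_two_sided(contingency_table(1, 1, 1, 1)), 1)
})

test_that("Fisher test equals full margin enumeration on random tables", {
  set.seed(19)
  for (rep in 1:40) {
    m <- matrix(sample(0:10, 4, replace = TRUE), 2)
    if (sum(m) == 0) next
    p <- fisher_exact_two_sided(m)
    expect_gt(p, 0)
    expect_lte(p, 1)
    expect_equal(p, oracle_fisher(m), tolerance = 1e-7)
    # simultaneous row and column swap leaves the table equivalent
    swapped <- m[2:1, 2:1]
    expect_equal(fisher_exact_two_sided(swapped), p, tolerance = 1e-12)
  }
  expect_error(contingency_table(-1, 2, 3, 4), "non-negative")
})

test_that("pooled-sample ROC reproduces the published discrimination", {
  dat <- pooled_math(table1_fixture())
  expect_equal(nrow(dat), 34L)
  roc <- roc_auc(dat$score, dat$label)
  expect_equal(roc$auc, 186 / 208)
  expect_equal(round(roc$auc, 2), 0.89)
})

test_that("AUC equals brute-force pair counting and flips under label swap", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(4:40, 1)
    scores <- round(runif(n, 0, 100), sample(0:2, 1))
    labels <- sample(c("CSM", "NCSM"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    auc <- roc_auc(scores, labels)$auc
    expect_equal(auc, oracle_auc(scores, labels, "NCSM"))
    flipped <- ifelse(labels == "CSM", "NCSM", "CSM")
    expect_equal(auc + roc_auc(scores, flipped)$auc, 1)
  }
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c("CSM", "CSM", "CSM", "NCSM",
                                             "NCSM"))$auc, 1)
  expect_equal(roc_auc(rep(5, 6), rep(c("CSM", "NCSM"), 3))$auc, 0.5)
  expect_error(roc_auc(1:3, rep("CSM", 3)), "at least one")
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  dat <- pooled_math(table1_fixture())
  ref <- pROC::auc(pROC::roc(response = dat$label, predictor = dat$score,
                             levels = c("CSM", "NCSM"), direction = "<",
                             quiet = TRUE))
  expect_equal(roc_auc(dat$score, dat$label)$auc, as.numeric(ref))
})

test_that("threshold rule reproduces the published operating point", {
  dat <- pooled_math(table1_fixture())
  cm <- confusion_at_threshold(dat$score, dat$label, 58)
  expect_equal(cm$sensitivity, 18 / 26)
  expect_equal(round(cm$sensitivity, 2), 0.69)
  expect_equal(cm$specificity, 1)
  # the rule is strictly score < threshold: nothing sits below 0
  cm0 <- confusion_at_threshold(dat$score, dat$label, 0)
  expect_equal(cm0$sensitivity, 0)
  expect_equal(cm0$specificity, 1)
  cmInf <- confusion_at_threshold(dat$score, dat$label, Inf)
  expect_equal(cmInf$sensitivity, 1)
  expect_equal(cmInf$specificity, 0)
})

test_that("Youden-optimal interval brackets the published threshold", {
  dat <- pooled_math(table1_fixture())
  oi <- youden_threshold(dat$score, dat$label)
  expect_equal(oi$low, 57.84)
  expect_equal(oi$high, 59.7)
  expect_true(oi$low < 58 && 58 <= oi$high)
  # perfectly separated classes: the interval is the between-class gap
  sep <- youden_threshold(c(1, 2, 3, 10, 11),
                          c("CSM", "CSM", "CSM", "NCSM", "NCSM"))
  expect_equal(sep$low, 3)
  expect_equal(sep$high, 10)
  expect_equal(sep$j, 1)
  # all ties: no threshold helps
  ties <- youden_threshold(rep(5, 6), rep(c("CSM", "NCSM"), 3))
  expect_equal(ties$j, 0)
})

test_that("any point inside the Youden interval achieves the maximal J", {
  set.seed(47)
  for (rep in 1:20) {
    n <- sample(6:40, 1)
    scores <- round(runif(n, 0, 100), 1)
    labels <- sample(c("CSM", "NCSM"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    oi <- youden_threshold(scores, labels)
    jmax <- oracle_max_j(scores, labels, "NCSM", "CSM")
    expect_equal(oi$j, jmax, tolerance = 1e-9)
    inside <- if (is.finite(oi$low)) {
      (oi$low + min(oi$high, oi$low + 1)) / 2
    } else oi$high
    cm <- confusion_at_threshold(scores, labels, inside)
    expect_equal(cm$sensitivity + cm$specificity - 1, jmax,
                 tolerance = 1e-9)
    # the interval brackets at least one midpoint of adjacent scores
    s <- sort(unique(scores))
    mids <- c(s[1] - 1, (head(s, -1) + tail(s, -1)) / 2,
              s[length(s)] + 1)
    expect_true(any(mids > oi$low & mids <= oi$high))
  }
})

test_that("group summaries use the printed conventions", {
  records <- table1_fixture()
  pre <- vapply(records, function(r) math_value(r$pre$math), 0)
  post <- vapply(records, function(r) math_value(r$post$math), 0)
  expect_equal(round(group_mean(pre), 2), 52.67)
  expect_equal(round(group_mean(post), 2), 64.05)
  dat <- pooled_math(records)
  expect_equal(group_lower_median(dat$score[dat$label == "CSM"]), 39.66)
  expect_equal(group_lower_median(dat$score[dat$label == "NCSM"]), 102.7)
  expect_equal(group_lower_median(c(1, 2, 3, 4)), 2)
  expect_error(group_mean(numeric(0)), "empty")
})

test_that("rank-sum test separates the shrinkage-mode groups on the cohort", {
  gt <- math_group_test(table1_fixture())
  expect_lt(gt$p_value, 0.01)
  expect_equal(gt$median_csm, 39.66)
  expect_equal(gt$median_ncsm, 102.7)
  expect_equal(gt$n_csm, 26L)
  expect_equal(gt$n_ncsm, 8L)
})

test_that("gene-set partition is a disjoint cover of the union", {
  p <- partition_gene_sets(c("A", "B"), c("B", "C"))
  expect_equal(p, list(pre_only = "A", shared = "B", post_only = "C"))
  empty <- partition_gene_sets(character(), character())
  expect_equal(lengths(empty), c(pre_only = 0L, shared = 0L,
                                 post_only = 0L))
  set.seed(53)
  for (rep in 1:20) {
    pre <- sample(LETTERS, sample(0:20, 1))
    post <- sample(LETTERS, sample(0:20, 1))
    parts <- partition_gene_sets(pre, post)
    expect_equal(sum(lengths(parts)), length(union(pre, post)))
    expect_length(intersect(parts$pre_only, parts$post_only), 0)
    expect_length(intersect(parts$pre_only, parts$shared), 0)
  }
})

make_flag_cohort <- function(pre_flags, post_flags, modes, gene = "TP53") {
  # one synthetic patient per flag pair; mutated samples carry one call
  lapply(seq_along(modes), function(i) {
    mk <- function(id, tp, mutated) {
      calls <- if (mutated) {
        make_call(0.3, gene = gene, sample_id = id)
      } else {
        make_call(0.3, gene = "OTHER", sample_id = id)
      }
      tumor_sample(id, tp, variants = calls)
    }
    patient_record(
      pre = mk(sprintf("P%d_pre", i), "pre_nac", pre_flags[i]),
      post = mk(sprintf("P%d_post", i), "post_nac", post_flags[i]),
      subtype = "luminal_A", mode = modes[i]
    )
  })
}

test_that("mutation frequency tables recover planted carrier counts", {
  modes <- rep(c("CSM", "NCSM"), c(13, 4))
  # plant the published TP53 pattern: pre 9/13 vs 2/4, post 4/13 vs 4/4
  pre_flags <- c(rep(TRUE, 9), rep(FALSE, 4), TRUE, TRUE, FALSE, FALSE)
  post_flags <- c(rep(TRUE, 4), rep(FALSE, 9), rep(TRUE, 4))
  records <- make_flag_cohort(pre_flags, post_flags, modes)
  pre_tab <- mutation_frequency_table(records, "TP53", "pre_nac")
  expect_equal(as.vector(unclass(pre_tab)), c(9L, 2L, 4L, 2L))
  post_tab <- mutation_frequency_table(records, "TP53", "post_nac")
  expect_equal(as.vector(unclass(post_tab)), c(4L, 4L, 9L, 0L))
  expect_equal(round(fisher_exact_two_sided(post_tab), 3), 0.029)
  # a known gene with no carriers at a timepoint gives a zero column
  none <- mutation_frequency_table(records, "TP53", "post_nac",
                                   genes = c("TP53", "GATA3"))
  expect_equal(sum(unclass(none)[, "mutated"]), 8L)
  zero <- mutation_frequency_table(
    make_flag_cohort(c(TRUE, TRUE), c(FALSE, FALSE), c("CSM", "NCSM")),
    "TP53", "post_nac")
  expect_equal(as.vector(unclass(zero)[, "mutated"]), c(0L, 0L))
  expect_error(mutation_frequency_table(records, "NOSUCHGENE", "pre_nac"),
               "unknown gene")
})
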