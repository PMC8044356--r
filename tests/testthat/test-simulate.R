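test_that("a fixed seed reproduces the cohort exactly", {
  cfg <- simulation_config(n_patients = 8, seed = 5)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(lapply(a$records, function(r) r$pre$variants),
                   lapply(b$records, function(r) r$pre$variants))
  expect_identical(vapply(a$truth, `[[`, "", "mode"),
                   vapply(b$truth, `[[`, "", "mode"))
})

test_that("a homogeneous noiseless tumor scores MATH 0 and shrinks concentrically", {
  cfg <- simulation_config(n_patients = 6, seed = 9, depth = Inf,
                           arm_high_prob = 0, clones_low = c(1, 1),
                           clones_high = c(6, 10),
                           contaminant_rate = 0, decoy_rate = 0,
                           label_noise = 0)
  sim <- simulate_cohort(cfg)
  for (i in seq_along(sim$records)) {
    r <- sim$records[[i]]
    expect_equal(math_value(r$pre$math), 0)
    expect_equal(r$mode, "CSM")
    vafs <- r$pre$variants$vaf
    expect_equal(length(unique(vafs)), 1L)  # one clone, no read noise
  }
})

test_that("planted contaminants are exactly the calls the population-frequency rule removes", {
  sim <- simulate_cohort(simulation_config(n_patients = 12, seed = 13))
  for (i in seq_along(sim$records)) {
    r <- sim$records[[i]]
    tr <- sim$truth[[i]]
    for (side in c("pre", "post")) {
      calls <- r[[side]]$variants
      removed_by_popfreq <- which(!is.na(calls$pop_freq_max) &
                                    calls$pop_freq_max > 0.05)
      planted <- tr[[paste0(side, "_contaminant_idx")]]
      expect_equal(removed_by_popfreq, planted)
    }
  }
})

test_that("with no contaminants the filter removes only sub-threshold VAFs", {
  sim <- simulate_cohort(simulation_config(n_patients = 10, seed = 17,
                                           contaminant_rate = 0))
  for (r in sim$records) {
    calls <- r$pre$variants
    kept <- filter_variants(calls)
    removed <- setdiff(seq_len(nrow(calls)),
                       which(rownames(calls) %in% rownames(kept)))
    low_vaf <- which(!(calls$vaf > 0.005 |
                         (calls$hotspot & calls$vaf > 0.001)))
    expect_setequal(removed, low_vaf)
  }
})

test_that("emitted cohorts satisfy the generative invariants", {
  sim <- simulate_cohort(simulation_config(n_patients = 25, seed = 19))
  for (i in seq_along(sim$records)) {
    r <- sim$records[[i]]
    tr <- sim$truth[[i]]
    for (side in c("pre", "post")) {
      vafs <- r[[side]]$variants$vaf
      expect_true(all(vafs >= 0 & vafs <= 1))
    }
    # filtered samples only empty down the pCR branch
    post_kept <- filter_variants(r$post$variants)
    if (nrow(post_kept) == 0L) expect_true(tr$pcr)
    expect_gt(nrow(filter_variants(r$pre$variants)), 0L)
    # diameters always agree with the assigned mode
    expect_equal(classify_shrinkage(r$d_pre_cm, r$d_post_cm)$mode, r$mode)
    # truth CCFs are a normalised mixture
    expect_equal(sum(tr$ccf), 1, tolerance = 1e-12)
  }
})

test_that("label noise flips modes at the configured rate", {
  sim <- simulate_cohort(simulation_config(n_patients = 200, seed = 23,
                                           label_noise = 0.5))
  flipped <- vapply(sim$truth, `[[`, TRUE, "flipped")
  expect_gt(mean(flipped), 0.35)
  expect_lt(mean(flipped), 0.65)
  agree <- vapply(sim$truth, function(t) t$mode == t$true_mode, TRUE)
  expect_equal(agree, !flipped)
})

test_that("written cohorts round-trip through the package readers", {
  dir <- withr::local_tempdir()
  sim <- simulate_cohort(simulation_config(n_patients = 6, seed = 29),
                         dir = dir)
  calls <- read_variant_table(file.path(dir, "variants.tsv"), "tsv")
  # every sample with at least one call appears (a pCR sample may have none)
  nonempty <- unlist(lapply(sim$records, function(r) {
    c(if (nrow(r$pre$variants) > 0) r$pre$sample_id,
      if (nrow(r$post$variants) > 0) r$post$sample_id)
  }))
  expect_setequal(unique(calls$sample_id), nonempty)
  back <- read_cohort_report(dir)
  expect_equal(vapply(back, `[[`, "", "mode"),
               vapply(sim$records, `[[`, "", "mode"))
  truth <- read.delim(file.path(dir, "truth.tsv"))
  expect_equal(nrow(truth), 6L)
  expect_true(all(truth$mode %in% c("CSM", "NCSM")))
})

test_that("expected MATH rises with CCF dispersion across arms", {
  means <- vapply(c(0.1, 0.2, 0.4, 0.8), function(d) {
    sim <- simulate_cohort(simulation_config(n_patients = 200, seed = 77,
                                             arm_high_prob = 1,
                                             ccf_dispersion = d))
    mean(unlist(lapply(sim$records, function(r) {
      c(math_value(r$pre$math), math_value(r$post$math))
    })))
  }, 0)
  expect_true(all(diff(means) > 0))
})

test_that("the planted response threshold is recovered by the Youden sweep", {
  cfg <- simulation_config(n_patients = 250, seed = 101, label_noise = 0)
  sim <- simulate_cohort(cfg)
  dat <- pooled_math(sim$records)
  oi <- youden_threshold(dat$score, dat$label)
  # containment up to one adjacent score gap: boundary tumors can be
  # carried across theta by read noise
  s <- sort(unique(dat$score))
  gap_low <- if (any(s < oi$low)) oi$low - max(s[s < oi$low]) else 0
  gap_high <- if (any(s > oi$high)) min(s[s > oi$high]) - oi$high else 0
  theta <- cfg$response_threshold
  expect_gt(theta, oi$low - gap_low)
  expect_lte(theta, oi$high + gap_high)
})

test_that("observed AUC matches the generative separation probability", {
  n <- 250
  lo <- simulate_cohort(simulation_config(n_patients = n, seed = 31,
                                          arm_high_prob = 1,
                                          ccf_dispersion = 0.3))
  hi <- simulate_cohort(simulation_config(n_patients = n, seed = 32,
                                          arm_high_prob = 1,
                                          ccf_dispersion = 0.6))
  obs <- c(vapply(lo$records, function(r) math_value(r$pre$math), 0),
           vapply(hi$records, function(r) math_value(r$pre$math), 0))
  tru <- c(vapply(lo$truth, `[[`, 0, "math_pre_true"),
           vapply(hi$truth, `[[`, 0, "math_pre_true"))
  labels <- rep(c("low", "high"), each = n)
  auc_obs <- roc_auc(obs, labels, positive = "high", negative = "low")$auc
  auc_true <- roc_auc(tru, labels, positive = "high",
                      negative = "low")$auc
  expect_lt(abs(auc_obs - auc_true), 0.03)
})
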