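#' Configuration for the subclonal cohort simulator
#'
#' The generative model behind the synthetic cohorts: each patient's tumor
#' is a mixture of subclonal populations; every somatic variant is private
#' to one clone and its true allele fraction at a heterozygous diploid site
#' is `purity * ccf / 2`, where the cancer-cell fraction (CCF) of a clone
#' is its share of the cancer-cell population. Sequencing adds binomial
#' read noise at the panel's mean depth. Chemotherapy eliminates clones at
#' random, the post-NAC sample is drawn from the survivors, and the
#' shrinkage mode is coupled to heterogeneity: concentric shrinkage iff the
#' noise-free MATH of both timepoints falls below `response_threshold`.
#'
#' @param n_patients Number of patients (default 17, the study cohort size).
#' @param seed Master seed; fixes the entire stream, with one substream per
#'   patient so cohorts are reproducible under parallel generation.
#' @param purity_range Tumor-purity interval, uniform draw (default
#'   0.4-0.9).
#' @param depth Mean sequencing depth of the targeted panel (default 1000);
#'   per-site depths are Poisson. `Inf` disables read noise.
#' @param arm_high_prob Probability that a patient's tumor belongs to the
#'   high-heterogeneity arm (default 0.25). Tumor cohorts of this kind are
#'   a mixture of two populations — low-heterogeneity tumors with few,
#'   comparably sized clones and high-heterogeneity tumors with many
#'   clones of widely dispersed size — and the per-patient arm is the
#'   latent driver that couples pre- and post-NAC heterogeneity within a
#'   patient.
#' @param clones_low,clones_high Inclusive clone-count range per
#'   heterogeneity arm: integer length-2 vectors, default `c(1, 3)` clones
#'   for a low-arm tumor and `c(6, 10)` for a high-arm tumor.
#' @param ccf_dispersion Positive scale of the per-tumor CCF-spread
#'   parameter. Each tumor draws a dispersion `d ~ Gamma(shape 6)` with
#'   mean `ccf_dispersion` in the high arm and `ccf_dispersion / 5` in the
#'   low arm; clone weights then decay geometrically with clone rank,
#'   `w_j \propto exp(-d (j - 1))` times a mild uniform jitter, and are
#'   normalised to CCFs. `d = 0` makes all clones equal-sized (homogeneous
#'   allele fractions, MATH near 0); larger values spread the CCFs and
#'   raise MATH at both timepoints. Default 0.8. (Well beyond ~1.2 the
#'   trailing clones fall below the VAF detection cutoff and realised MATH
#'   saturates; see the package vignette.)
#' @param variants_per_clone Poisson mean of the somatic variant count per
#'   clone (default 6; the dominant clone always carries at least one).
#' @param contaminant_rate Expected number of population-polymorphism
#'   contaminants (`pop_freq_max > 0.05`) per somatic variant (default
#'   0.1).
#' @param decoy_rate Expected number of sub-threshold-VAF artifact calls
#'   per somatic variant (default 0.1).
#' @param hotspot_rate Probability a somatic variant is flagged as a cancer
#'   hotspot (default 0.15).
#' @param response_threshold MATH level coupling heterogeneity to the
#'   shrinkage mode (default 58).
#' @param label_noise Probability of flipping the generated mode label
#'   (default 0).
#' @param elim_intercept,elim_slope,elim_dispersion_penalty Parameters of
#'   the clone-elimination probability, logistic in the clone's CCF rank:
#'   `plogis(elim_intercept - elim_slope * (rank - 1) -
#'   elim_dispersion_penalty * d)` with `d` the tumor's own dispersion, so
#'   dominant clones respond best and high-dispersion tumors respond less.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 17, seed = 1,
                              purity_range = c(0.4, 0.9), depth = 1000,
                              arm_high_prob = 0.25,
                              clones_low = c(1, 3), clones_high = c(6, 10),
                              ccf_dispersion = 0.8, variants_per_clone = 6,
                              contaminant_rate = 0.1, decoy_rate = 0.1,
                              hotspot_rate = 0.15,
                              response_threshold = 58, label_noise = 0,
                              elim_intercept = 2, elim_slope = 0.8,
                              elim_dispersion_penalty = 6) {
  if (length(clones_low) == 1L) clones_low <- rep(clones_low, 2)
  if (length(clones_high) == 1L) clones_high <- rep(clones_high, 2)
  stopifnot(n_patients >= 1, length(purity_range) == 2,
            purity_range[1] > 0, purity_range[2] <= 1,
            purity_range[1] <= purity_range[2],
            depth > 0, arm_high_prob >= 0, arm_high_prob <= 1,
            length(clones_low) == 2, length(clones_high) == 2,
            clones_low[1] >= 1, clones_low[1] <= clones_low[2],
            clones_high[1] >= 1, clones_high[1] <= clones_high[2],
            ccf_dispersion >= 0, variants_per_clone > 0,
            contaminant_rate >= 0, decoy_rate >= 0,
            hotspot_rate >= 0, hotspot_rate <= 1,
            response_threshold > 0,
            label_noise >= 0, label_noise <= 1)
  structure(list(n_patients = as.integer(n_patients),
                 seed = as.integer(seed), purity_range = purity_range,
                 depth = depth, arm_high_prob = arm_high_prob,
                 clones_low = as.integer(clones_low),
                 clones_high = as.integer(clones_high),
                 ccf_dispersion = ccf_dispersion,
                 variants_per_clone = variants_per_clone,
                 contaminant_rate = contaminant_rate,
                 decoy_rate = decoy_rate, hotspot_rate = hotspot_rate,
                 response_threshold = response_threshold,
                 label_noise = label_noise,
                 elim_intercept = elim_intercept, elim_slope = elim_slope,
                 elim_dispersion_penalty = elim_dispersion_penalty),
            class = "simulation_config")
}

## run expr under a local seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## a small cancer-gene panel; recurrent breast-cancer drivers are weighted
## up so hot genes dominate, as in targeted-panel cohorts
panel_genes <- function() {
  genes <- c("TP53", "PIK3CA", "BRCA1", "BRCA2", "NOTCH1", "ACVR2A",
             "CSF1R", "JAK2", "MAP3K1", "MECOM", "PAX5", "PTEN", "GATA3",
             "CDH1", "AKT1", "ERBB2", "ERBB3", "KMT2C", "ARID1A", "ESR1",
             "RB1", "NF1", "FGFR1", "FGFR2", "CCND1", "MYC", "EGFR",
             "KRAS", "NRAS", "BRAF", "ATM", "CHEK2", "PALB2", "SF3B1",
             "RUNX1", "TBX3", "FOXA1", "CBFB", "PTPN11", "SMAD4")
  weights <- c(8, 6, rep(2, 10), rep(1, length(genes) - 12))
  list(genes = genes, weights = weights / sum(weights))
}

random_alleles <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
  list(ref = ref, alt = unname(alt))
}

observe_vaf <- function(true_vaf, depth) {
  if (is.infinite(depth)) return(true_vaf)
  dp <- pmax(stats::rpois(length(true_vaf), depth), 1L)
  stats::rbinom(length(true_vaf), dp, pmin(true_vaf, 1)) / dp
}

make_calls <- function(sample_id, true_vaf, cfg, clone, kind) {
  n <- length(true_vaf)
  if (n == 0L) {
    df <- variant_calls()
    df$clone <- integer()
    df$kind <- character()
    df$true_vaf <- numeric()
    return(df)
  }
  panel <- panel_genes()
  al <- random_alleles(n)
  pop <- switch(kind,
    somatic = ifelse(stats::runif(n) < 0.8, 0, stats::runif(n, 0, 0.05)),
    contaminant = stats::runif(n, 0.06, 0.5),
    decoy = rep(0, n))
  hotspot <- switch(kind,
    somatic = stats::runif(n) < cfg$hotspot_rate,
    rep(FALSE, n))
  df <- variant_calls(
    sample_id = sample_id,
    gene = sample(panel$genes, n, replace = TRUE, prob = panel$weights),
    chrom = as.character(sample(1:22, n, replace = TRUE)),
    pos = sample.int(2e8, n, replace = TRUE),
    ref = al$ref, alt = al$alt,
    vaf = observe_vaf(true_vaf, cfg$depth),
    pop_freq_max = pop,
    effect = sample(c("nonsynonymous_snv", "stopgain", "frameshift",
                      "splicing"), n, replace = TRUE,
                    prob = c(0.7, 0.1, 0.1, 0.1)),
    hotspot = hotspot
  )
  df$clone <- clone
  df$kind <- kind
  df$true_vaf <- true_vaf
  df
}

#' Simulate one patient: paired pre/post-NAC samples plus ground truth
#'
#' Draws a clone mixture, a pre-NAC sample from all clones and a post-NAC
#' sample from the clones surviving a random elimination step, plants
#' population-polymorphism contaminants and sub-threshold-VAF decoys,
#' assigns the shrinkage mode from the noise-free MATH of both timepoints
#' against `cfg$response_threshold` (flipped with probability
#' `cfg$label_noise`), and draws tumor diameters consistent with the final
#' mode. The molecular subtype is produced by pushing a random IHC profile
#' through [assign_subtype()].
#'
#' The returned variant tables carry three extra provenance columns beyond
#' the `variant_calls` schema — `clone`, `kind` (`"somatic"`,
#' `"contaminant"`, `"decoy"`) and `true_vaf` — mirrored in the truth
#' object for recovery tests.
#'
#' @param cfg A [simulation_config()].
#' @param patient_id Integer patient index (names the samples).
#' @param seed Seed for this patient's substream.
#' @return List with `record` (a [patient_record()], samples scored via
#'   the standard filter + MATH pipeline) and `truth` (clone CCFs, purity,
#'   true noise-free MATH values, pre-flip and final mode, eliminated
#'   clones, planted contaminant/decoy row indices).
#' @export
simulate_patient <- function(cfg, patient_id = 1L, seed = cfg$seed) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_local_seed(seed, {
    purity <- stats::runif(1, cfg$purity_range[1], cfg$purity_range[2])
    arm <- if (stats::runif(1) < cfg$arm_high_prob) "high" else "low"
    clone_range <- if (arm == "low") {
      seq(cfg$clones_low[1], cfg$clones_low[2])
    } else {
      seq(cfg$clones_high[1], cfg$clones_high[2])
    }
    n_clones <- clone_range[sample.int(length(clone_range), 1)]
    disp_mean <- cfg$ccf_dispersion * if (arm == "low") 0.2 else 1
    disp <- if (disp_mean == 0) 0 else {
      stats::rgamma(1, shape = 6, scale = disp_mean / 6)
    }
    w <- exp(-disp * (seq_len(n_clones) - 1)) *
      stats::runif(n_clones, 0.7, 1.3)
    ccf <- sort(w / sum(w), decreasing = TRUE)
    n_var <- stats::rpois(n_clones, cfg$variants_per_clone)
    n_var[1] <- max(n_var[1], 1L)  # the dominant clone is never silent

    pre_id <- sprintf("P%03d_pre", patient_id)
    post_id <- sprintf("P%03d_post", patient_id)

    clone_of <- rep(seq_len(n_clones), n_var)
    pre_true <- purity * ccf[clone_of] / 2
    pre_somatic <- make_calls(pre_id, pre_true, cfg, clone_of, "somatic")

    ## chemotherapy: clone ranked r by CCF survives unless eliminated
    p_elim <- stats::plogis(cfg$elim_intercept -
                              cfg$elim_slope * (seq_len(n_clones) - 1) -
                              cfg$elim_dispersion_penalty * disp)
    eliminated <- stats::runif(n_clones) < p_elim
    survivors <- which(!eliminated)
    if (length(survivors) > 0L) {
      ccf_post <- ccf[survivors] / sum(ccf[survivors])
      post_clone <- rep(survivors, n_var[survivors])
      post_true <- purity * ccf_post[match(post_clone, survivors)] / 2
      post_somatic <- make_calls(post_id, post_true, cfg, post_clone,
                                 "somatic")
    } else {
      post_true <- numeric()
      post_somatic <- make_calls(post_id, numeric(), cfg, integer(),
                                 "somatic")
    }

    plant <- function(base, sample_id, rate, kind) {
      n <- stats::rpois(1, rate * max(nrow(base), 1))
      if (n == 0L) return(base)
      tv <- switch(kind,
        contaminant = stats::rbeta(n, 20, 20),     # germline-like het VAF
        decoy = stats::runif(n, 5e-4, 4e-3))       # below the 0.5% cutoff
      rbind(base, make_calls(sample_id, tv, cfg, NA_integer_, kind))
    }
    pre_calls <- plant(plant(pre_somatic, pre_id, cfg$contaminant_rate,
                             "contaminant"),
                       pre_id, cfg$decoy_rate, "decoy")
    post_calls <- plant(plant(post_somatic, post_id, cfg$contaminant_rate,
                              "contaminant"),
                        post_id, cfg$decoy_rate, "decoy")

    ## noise-free heterogeneity: MATH of the true VAFs the retention rules
    ## would keep at infinite depth — the quantity the pipeline estimates
    detectable <- function(calls) {
      calls$true_vaf[calls$true_vaf > 0.005 |
                       (calls$hotspot & calls$true_vaf > 0.001)]
    }
    math_pre_true <- compute_math(detectable(pre_somatic))
    math_post_true <- compute_math(detectable(post_somatic))
    true_mode <- if (math_pre_true$value < cfg$response_threshold &&
                       math_post_true$value < cfg$response_threshold) {
      "CSM"
    } else "NCSM"
    flipped <- stats::runif(1) < cfg$label_noise
    mode <- if (flipped) setdiff(mode_levels(), true_mode) else true_mode

    ## diameters drawn conditional on the final mode so the size rule and
    ## the label always agree
    d_pre <- stats::runif(1, 2, 8)
    pcr <- length(survivors) == 0L
    d_post <- if (mode == "CSM") {
      if (pcr) 0 else min(2, d_pre * stats::runif(1, 0.1, 0.5))
    } else {
      d_pre * stats::runif(1, 0.55, 0.95)
    }
    submode <- classify_shrinkage(d_pre, d_post)$submode

    ihc <- list(er = sample(c(0, 0, 5, 40, 90), 1),
                pr = sample(c(0, 0, 10, 60), 1),
                her2 = sample(0:3, 1),
                fish = stats::runif(1) < 0.5,
                ki67 = stats::runif(1, 0, 80))
    subtype <- assign_subtype(ihc$er, ihc$pr, ihc$her2, ihc$fish, ihc$ki67)

    record <- patient_record(
      pre = score_sample(tumor_sample(pre_id, "pre_nac",
                                      variants = pre_calls)),
      post = if (nrow(post_calls) == 0L ||
                   nrow(filter_variants(post_calls)) == 0L) {
        smp <- tumor_sample(post_id, "post_nac", variants = post_calls)
        smp$math <- compute_math(numeric())
        smp
      } else {
        score_sample(tumor_sample(post_id, "post_nac",
                                  variants = post_calls))
      },
      subtype = subtype, d_pre_cm = d_pre, d_post_cm = d_post,
      mode = mode, submode = submode
    )
    truth <- list(patient_id = patient_id, arm = arm, purity = purity,
                  n_clones = n_clones, ccf = ccf,
                  ccf_dispersion = disp,
                  eliminated = which(eliminated),
                  math_pre_true = math_pre_true$value,
                  math_post_true = math_post_true$value,
                  true_mode = true_mode, mode = mode, flipped = flipped,
                  pcr = pcr,
                  pre_contaminant_idx = which(pre_calls$kind ==
                                                "contaminant"),
                  post_contaminant_idx = which(post_calls$kind ==
                                                 "contaminant"),
                  pre_decoy_idx = which(pre_calls$kind == "decoy"),
                  post_decoy_idx = which(post_calls$kind == "decoy"))
    list(record = record, truth = truth)
  })
}

#' Simulate a full cohort, optionally writing it to disk
#'
#' Runs [simulate_patient()] once per patient on independent substreams
#' derived from the master seed. With `dir` given, writes the cohort in the
#' package's on-disk formats: `variants.tsv` (the [read_variant_table()]
#' TSV schema, provenance columns dropped), `patients.tsv` (via
#' [write_cohort_report()]) and `truth.tsv` (per-patient ground-truth
#' summary).
#'
#' @param cfg A [simulation_config()].
#' @param dir Optional output directory.
#' @return List with `records` (list of [patient_record()]), `truth` (list
#'   of per-patient truth objects) and `config`.
#' @examples
#' cohort <- simulate_cohort(simulation_config(n_patients = 4, seed = 7))
#' pooled_math(cohort$records)
#' @export
simulate_cohort <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  seeds <- with_local_seed(cfg$seed,
                           sample.int(.Machine$integer.max - 1L,
                                      cfg$n_patients))
  sims <- lapply(seq_len(cfg$n_patients), function(i) {
    simulate_patient(cfg, patient_id = i, seed = seeds[i])
  })
  records <- lapply(sims, `[[`, "record")
  truth <- lapply(sims, `[[`, "truth")
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    all_calls <- do.call(rbind, unlist(lapply(records, function(r) {
      pre <- r$pre$variants
      pre$timepoint <- rep("pre_nac", nrow(pre))
      post <- r$post$variants
      post$timepoint <- rep("post_nac", nrow(post))
      list(pre, post)
    }), recursive = FALSE))
    schema <- c("sample_id", "timepoint", "gene", "chrom", "pos", "ref",
                "alt", "vaf", "pop_freq_max", "effect", "hotspot")
    write_variant_table(all_calls[, schema], file.path(dir, "variants.tsv"))
    write_cohort_report(records, dir)
    truth_tab <- do.call(rbind, lapply(truth, function(tr) {
      data.frame(patient_id = tr$patient_id, arm = tr$arm,
                 purity = tr$purity, n_clones = tr$n_clones,
                 ccf = paste(signif(tr$ccf, 6), collapse = ","),
                 eliminated = paste(tr$eliminated, collapse = ","),
                 math_pre_true = tr$math_pre_true,
                 math_post_true = tr$math_post_true,
                 true_mode = tr$true_mode, mode = tr$mode,
                 flipped = tr$flipped, pcr = tr$pcr,
                 stringsAsFactors = FALSE)
    }))
    write.table(truth_tab, file.path(dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(records = records, truth = truth, config = cfg)
}
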