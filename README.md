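# mathshrink

Intra-tumor genetic heterogeneity, quantified from targeted-panel somatic
variant calls by the **mutant-allele tumor heterogeneity (MATH)**
statistic, as a predictor of the **tumor shrinkage mode** after
neoadjuvant chemotherapy (NAC) in breast cancer.

Tumors regress under NAC either *concentrically* (CSM — residual ≤ 2 cm
with ≥ 50% reduction of the longest diameter; favorable for
breast-conserving surgery) or *non-concentrically* (NCSM). This package
implements, as tested reusable functions, the full analysis chain linking
heterogeneity to that dichotomy: somatic-variant retention rules, MATH
scoring, shrinkage-mode and molecular-subtype classification, cohort-level
inference (Fisher exact gene-frequency comparisons, pooled ROC/AUC,
Youden-threshold analysis, group summaries, gene-set partitions), and a
seedable subclonal cohort simulator so every stage is testable without
patient-level sequencing data.

## The statistic

For a sample's retained variant allele fractions $x_1,\dots,x_n$,

$$\mathrm{MATH} = 100 \cdot \frac{\mathrm{MAD}(x)}{\mathrm{median}(x)},
\qquad \mathrm{MAD}(x) = 1.4826 \cdot
\operatorname{median}_i\,|x_i - \operatorname{median}(x)|,$$

the percentage ratio of the width to the center of the mutant-allele-
fraction distribution. Calls feed the score iff the maximum population
allele frequency is ≤ 0.05, the functional class is protein-altering, and
the VAF exceeds 0.5% (0.1% for cancer-hotspot calls). A pooled MATH
threshold of 58 — applied to pre- and post-NAC samples alike, predicting
CSM when the score falls strictly below it — separates the two modes in
the packaged 17-patient cohort.

## Worked example

```r
library(mathshrink)

# MATH of a five-variant sample
compute_math(c(0.1, 0.2, 0.3, 0.4, 0.5))
#> MATH = 49.42  (n = 5, median VAF = 0.3000, MAD = 0.1483)

# the packaged 17-patient cohort: pool the 34 pre/post samples,
# each labeled with its patient's shrinkage mode
dat <- pooled_math(table1_fixture())
roc_auc(dat$score, dat$label)
#> ROC: AUC = 0.894 over 34 samples (8 positive)
#> Youden-optimal threshold interval: (57.84, 59.7], J = 0.692

unlist(confusion_at_threshold(dat$score, dat$label, 58))
#> sensitivity specificity
#>   0.6923077   1.0000000

# gene-frequency contrasts between the mode groups
sapply(table2_fixture(), function(t) round(fisher_exact_two_sided(t), 3))
#>    tp53_pre   tp53_post  pik3ca_pre pik3ca_post
#>       0.584       0.029       0.538       0.294
```

The AUC of 0.89 says a randomly chosen NCSM sample out-scores a randomly
chosen CSM sample 89% of the time; at the threshold of 58, 18 of 26 CSM
samples fall below (sensitivity 0.69) and all 8 NCSM samples fall at or
above (specificity 1). The Youden-optimal interval `(57.84, 59.7]` is the
full range of thresholds achieving that operating point. Of the four
gene-frequency contrasts only post-NAC TP53 reaches significance
(p = 0.029).

Synthetic cohorts with ground truth:

```r
sim <- simulate_cohort(simulation_config(n_patients = 3, seed = 42))
sim$records[[1]]
#> <patient_record> P001_pre/P001_post  luminal_A  mode=NCSM  MATH 97.41 -> 92.04
```

See the vignette (`vignettes/math-heterogeneity.Rmd`) for the generative
model, parameter meanings and calibration rationale.

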