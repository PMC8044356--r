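Package: mathshrink
Title: Mutant-Allele Tumor Heterogeneity and Shrinkage-Mode Analysis for
    Neoadjuvant Chemotherapy Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify intra-tumor genetic heterogeneity from
    targeted-panel somatic variant calls and relate it to the pathological
    shrinkage mode of breast tumors after neoadjuvant chemotherapy (NAC).
    Implements somatic variant retention rules based on variant allele
    fraction, population allele frequency and cancer-hotspot membership; the
    mutant-allele tumor heterogeneity (MATH) statistic, 100 times the scaled
    median absolute deviation over the median of a sample's mutant-allele
    fractions; concentric versus non-concentric shrinkage-mode classification
    from longest tumor diameters; molecular-subtype assignment from
    immunohistochemistry profiles; cohort-level inference (Fisher exact
    gene-frequency comparisons, pair-counting ROC/AUC, Youden-optimal
    threshold intervals, group summaries, pre/post gene-set partitions); and
    a seedable subclonal cohort simulator for end-to-end validation without
    access to patient-level sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
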