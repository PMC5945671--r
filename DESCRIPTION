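Package: scarsig
Title: Mutational Signature Refitting, Purity/Ploidy Estimation and Genomic
    Scar Scores for Multiregion Tumor Exomes
Version: 0.1.0
Authors@R:
    person("scarsig", "authors", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the downstream analysis of multiregion tumor
    whole-exome sequencing: construction of strand-bias-filtered 96-channel
    mutational catalogues with target-capture triplet correction, supervised
    decomposition into predefined mutational signatures by two-pass
    non-negative least squares with signature-specific cutoffs (including
    ROC-based cutoff calibration), tumor cell content and ploidy estimation
    from coverage ratios and B-allele frequencies by constrained grid search
    with allele-specific copy numbers and decrease of heterozygosity,
    HRD-LOH and LST genomic-scar scores on smoothed copy-number profiles,
    primary-tumor versus thrombus mutation-sharing analysis, and a
    synthetic-data generator producing every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    GenomicRanges,
    SummarizedExperiment,
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
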