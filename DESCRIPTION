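Package: pdxmeth
Title: Methylome Fidelity Assessment for Patient-Derived Tumour Xenografts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing whether patient-derived tumour xenografts
    (PDXs) preserve the DNA methylome of the originating patient tumour,
    as measured on Infinium 450K-style beta-value matrices. Provides
    probe-level quality control with host (mouse) genome masking, the
    delta-beta "reversed methylation" statistic with a calibrated 0.51
    threshold, resampling-based (epi)genomic feature enrichment and
    probe-set overlap significance tests, classification of paired-end
    reads aligned against both graft and host genomes, a perturb-and-test
    Wilcoxon rank-sum sample-size simulation for two-group PDX study
    design, and a synthetic methylome generator that emulates the
    bimodal, feature-dependent structure of 450K data with planted
    xenografting-associated changes as ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    graphics,
    GenomicRanges,
    IRanges,
    jsonlite,
    Rcpp,
    Rsamtools,
    rtracklayer,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
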