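Package: mutorigin
Title: Cell-of-Origin Classification from Sparse Somatic Mutation Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Classifies the cell of origin of a tumor from sparse somatic
    single-nucleotide variant (SNV) profiles such as those recovered from
    liquid biopsies. Provides random SNV downsampling to emulate circulating
    tumor DNA sparsity, training-set augmentation by repeated subsampling,
    extraction of three SNV-derived feature types (1 Mb genome-wide mutation
    density bins, 96 pyrimidine-strand trinucleotide substitution contexts,
    and driver-gene mutation densities), feed-forward classifiers that
    integrate the feature types through early, multi-branch or consecutive
    wiring, Gaussian-process Bayesian hyperparameter search, donor-safe
    stratified shuffle-split cross-validation with per-class F1 and top-k
    accuracy, integrated-gradients feature attribution with log-modulus
    scaling, and a synthetic cohort generator that emits VCF, FASTA and
    manifest files so the whole pipeline can be exercised without access to
    controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    jsonlite,
    lhs,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    GenomicRanges,
    IRanges,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
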