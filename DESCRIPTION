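Package: hybploidy
Title: Ploidy Inference from Target-Capture Allele Depths
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates ploidy level (2x, 3x, 4x and higher) of individual
    samples from the allele balance of biallelic SNPs in target-capture
    (Hyb-Seq) sequencing data. Fits fixed-mean Gaussian mixture models for
    diploid, triploid and tetraploid hypotheses against a free mixture by
    expectation-maximization, validates calls with delta log-likelihoods and
    histogram-fit statistics (SSR, slope, standard error, R squared), and
    complements the mixture call with per-SNP allelic-ratio statistics
    (sample- and gene-level medians, quartiles, fraction of ratios below two)
    that flag higher ploidy levels and recent autopolyploids. Includes an
    analytic enumeration of expected allelic-ratio classes for any ploidy
    under a sequencing-noise threshold, bootstrap density envelopes from
    diploid references, a flow-cytometry genome-size helper, and a read-depth
    simulator that makes every stage testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    BiocGenerics,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
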