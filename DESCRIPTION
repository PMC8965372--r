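Package: rohmm
Title: Runs of Homozygosity from Windowed Heterozygosity via a Gaussian HMM
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genomic assessment of inbreeding in small, pedigree-managed
    populations from multi-sample VCF data. Applies site filters, computes
    window heterozygosity along the callable genome, fits a per-sample
    3-state Gaussian-emission hidden Markov model by Baum-Welch and segments
    putative runs of homozygosity (RoH) by Viterbi decoding. Derives genomic
    inbreeding coefficients (F_ROH, F_HOM), pedigree inbreeding and kinship
    by the tabular method, RoH colocalization (Jaccard coefficients, sharing
    spectrum), cross-estimator rank correlations and group comparisons.
    Includes a synthetic diploid-genome generator with planted autozygous
    tracts and gene-dropping through a pedigree, so every stage can be
    validated against ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
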