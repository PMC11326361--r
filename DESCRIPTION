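Package: rhyqtl
Title: Mapping Rhythmic Quantitative Trait Loci from Time-Stamped Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects genetic variants that modulate 24-hour rhythmic gene
    expression (rhythmic QTLs, or rhyQTLs). Provides cosinor (harmonic)
    regression at a fixed 24-h period, variant quality control (minor allele
    frequency, exact Hardy-Weinberg test), cis and trans variant-gene pairing
    around transcription start sites, a BIC-based model-selection statistic for
    differential rhythmicity between genotype groups with repeated equal-size
    downsampling and a G-test on selected-model frequencies, enrichment
    statistics (MAF-matched background sampling against baseline regions,
    motif and GWAS-tag odds ratios, LD extension, lead-SNP clumping and region
    classification), peak-phase summaries, and a synthetic-data generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    GenomicRanges,
    IRanges,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
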