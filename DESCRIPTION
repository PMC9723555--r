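Package: spuria
Title: Detection, Quantification and Filtering of Spurious Taxa in 16S
    rRNA Gene Amplicon Count Tables
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for handling spurious taxa (false-positive OTUs and
    ASVs) in high-throughput 16S rRNA gene amplicon profiling. Implements
    singleton removal and relative-abundance cutoff filtering of
    taxa-by-sample count tables, benchmarking of observed communities
    against reference (mock or gnotobiotic) communities via sequence
    identity, coverage or Hamming-distance matching, the effective
    microbial richness (EMR) statistic and other alpha-diversity
    readouts, reproducibility statistics (interquartile ranges and
    coefficients of variation of richness), unweighted and generalized
    UniFrac beta-diversity, prevalence and category-exclusivity analysis
    of spurious taxa across sequencing runs, and a synthetic-data
    generator that emulates contaminated amplicon sequencing studies
    with ground-truth labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    phangorn,
    stats,
    utils,
    vegan
Suggests:
    phyloseq,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
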