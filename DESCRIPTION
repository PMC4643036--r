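Package: durmiR
Title: Small RNA Profiling and Hairpin Discovery for Durum Wheat Water-Deficit Studies
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A tested re-implementation of a two-pronged small RNA-seq analysis
    for durum wheat under water deficit stress: conserved miRNA profiling with
    explicit RPM/fold-change differential-abundance criteria, de novo pre-miRNA
    hairpin discovery with an eight-category read-coverage classifier, and an
    empirical-Bayes moderated tolerance-by-treatment interaction test. Includes
    a synthetic-data generator that emulates the factorial study design
    (genotypes by tissues by treatments by replicates) with known ground truth
    for every downstream stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    limma,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
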