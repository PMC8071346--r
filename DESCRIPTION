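Package: bincnv
Title: Copy Number Variant Detection from Low-Coverage Whole-Genome
    Sequencing Bin Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects copy number variants (CNVs) from low-coverage
    whole-genome sequencing. Mapped reads are counted in fixed-size
    genomic bins, corrected for GC bias by locally weighted regression,
    denoised against a reference panel of non-aberrated samples via
    principal components, and segmented with a circular binary
    segmentation engine into color-coded significance classes. Includes
    a closed-form binomial power model linking read count, CNV length
    and detection Z-score, an in-silico CNV-injection framework that
    measures detection and coordinate accuracy over a read-count by
    CNV-length grid, and a synthetic-data generator emulating GC bias,
    low-rank cross-sample artifacts, unmappable regions and Poisson
    counting noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    Biostrings,
    optparse
Config/testthat/edition: 3
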