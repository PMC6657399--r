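Package: poolsweep
Title: Selective-Sweep Scans on Pooled Sequencing Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects candidate selective-sweep regions from two-group
    pool-seq allele counts. Computes pooled heterozygosity (HP) and FST in
    sliding genomic windows, Z-transforms both statistics genome-wide,
    intersects dual Z-score outliers, merges adjacent outlier windows into
    candidate regions and annotates them with overlapping genes. Also
    provides the SNP quality-control filters used upstream of the scan
    (site quality, inter-SNP spacing, read-depth bounds), a 2^-ddCt
    relative-expression module for qPCR follow-up of candidate genes, and
    a seeded simulator of pooled allele counts with planted sweeps for
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
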