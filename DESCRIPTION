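Package: sparsecnv
Title: Genome-Wide CNV, LOH and UPD Calling from Sparse Targeted Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls genome-wide copy-number variants (CNV), loss of
    heterozygosity (LOH) and copy-neutral uniparental disomy (UPD,
    isodisomy) from sparse, evenly spaced targeted-sequencing panels.
    Per-probe read depths are smoothed and normalized against a
    multi-sample median baseline (a panel of normals) in place of a
    matched control; probe- and region-level t tests with a run-length
    seeding and merging heuristic segment the genome and assign integer
    copy numbers, while a sliding-window F test on the heterozygosity
    coefficient of B-allele frequencies detects LOH and classifies
    copy-neutral events as isodisomy. Also included are the probe-design
    procedure for selecting an evenly spaced SNP-anchored target grid
    from a reference genome, a count-level simulator with implanted
    CNV/LOH/UPD truth for benchmarking, readers and writers for the BED,
    TSV and VCF dialects the pipeline consumes, and ggplot2/broom-style
    methods for inspecting results.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    withr,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    vcfR,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
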