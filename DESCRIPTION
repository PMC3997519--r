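Package: sRNAshuttle
Title: Nucleocytoplasmic Small RNA Profiling of Wolbachia-Infected Mosquito Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for nucleus-versus-cytoplasm small RNA
    sequencing analysis in Wolbachia-infected and uninfected Aedes aegypti
    cell lines: 3' adapter trimming and read collapsing, removal of
    Rfam/Repbase-like contaminants and mRNA degradation products, seeded
    mismatch-tolerant alignment to miRNA hairpin and piRNA references,
    isomiR classification against annotated mature sequences, library-size
    normalization (median-of-ratios or per-million), log2 fold-change tables
    with explicit infinite-fold conventions, nucleus/cytoplasm detection
    partitions and compartment-shift calls, and read-length class profiling
    (miRNA 18-22 nt, piRNA 26-30 nt). Includes a seeded synthetic four-library
    read simulator with full ground truth, and the published expression tables
    from the GSE55210 study for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
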