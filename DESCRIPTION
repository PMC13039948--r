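Package: m6Aland
Title: Site-Level Differential m6A Epitranscriptome Analysis from Direct RNA-Seq Pileups
Version: 0.1.0
Authors@R:
    person("m6Aland", "Developers", email = "m6aland@example.org", role = c("aut", "cre"))
Description: Tools for site-level analysis of N6-methyladenosine (m6A)
    stoichiometry from nanopore direct RNA sequencing modification pileups
    (modkit-style bedMethyl). Reads per-site modification counts per replicate,
    aggregates conditions, filters and calls m6A sites, maps sites onto
    transcript models (region, DRACH motif context, metagene position),
    computes differential sites with threshold counts stratified by region and
    motif class, classifies transcript isoforms by modified-read fraction,
    quantifies treatment-induced restoration of hypomethylated sites, ranks
    genes by average and net m6A change, runs preranked gene-set enrichment
    with a permutation null and hypergeometric overlap tests, integrates
    differential-expression tables across cell lines and m6A-reader binding
    intervals, and generates fully seeded synthetic corpora emulating the
    statistical structure of tumor/normal and treated/untreated direct RNA-seq
    comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    Biostrings,
    rtracklayer,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
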