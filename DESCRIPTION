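Package: evqc
Title: Quality Assessment and Cargo Enrichment Analysis for Extracellular
    Vesicle Small RNA Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end toolkit for assessing extracellular vesicle (EV)
    small RNA sequencing libraries: reference-free inference of 3' adapter
    patterns (adapter sequence plus degenerate bases at both insert ends),
    adapter and random-base trimming with a minimum-length filter, two-tier
    host/non-host assignment of inserts to small RNA biotypes (miRNA, tRNA,
    rRNA, Y RNA, snRNA, snoRNA, mt-tRNA, lincRNA, misc), per-sample quality
    gates and study-level variability summaries, biotype composition
    statistics with log2 abundance ratios, and EV-versus-donor-cell
    enrichment analysis via confounder-adjusted ANOVA on proportions and
    per-miRNA negative binomial differential abundance with
    Benjamini-Hochberg correction. A fully seeded synthetic-data generator
    produces reference catalogs, sample manifests, and FASTQ libraries with
    per-read ground truth so every stage can be validated without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    MASS,
    car,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
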