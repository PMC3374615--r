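Package: mcrispr
Title: CRISPR Array Detection and Targeted Assembly for Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for identifying and characterizing CRISPR arrays in
    metagenomic sequence data. Provides de novo array detection on contigs
    with recovery of incomplete repeats at contig ends, similarity-based
    array detection driven by a query repeat consensus, targeted assembly of
    CRISPR loci by repeat-based read recruitment into a long-k de Bruijn
    graph, catalog construction (selection filters, orientation-aware
    identity clustering, edit-distance repeat networks, body-site
    classification), spacer analytics (deduplication, clustering,
    cross-sample sharing, proto-spacer search against phage genomes and PAM
    flank profiling), and a synthetic-data generator that plants CRISPR loci
    into mock genomes and communities with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    Biostrings,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
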