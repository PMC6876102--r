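Package: mcia
Title: Significance Testing and Domain Calling for Multiplex Chromatin
    Interaction Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: De-noising and statistical analysis of single-molecule multiplex
    chromatin interaction data such as ChIA-Drop and SPRITE. Provides a
    resampling-based distance test with a normalized Shannon-entropy filter
    that detects barcode multiplets (doublets and triplets), a wavelet-based
    caller for topologically associating domains (TADs) that operates
    directly on multiplex complexes, an expanded-pair binomial test for
    frequent inter-TAD contacts, an empirical enrichment test for
    protein-enriched (e.g. RNA polymerase II) data, SPRITE cluster
    pre-processing, and a seeded synthetic-data generator with ground-truth
    labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
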