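Package: gpbwt
Title: Graph Positional Burrows-Wheeler Transform for Haplotype Threads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A compressed, searchable store of haplotype walks ("threads")
    embedded in a bidirected genome graph: the graph positional
    Burrows-Wheeler transform (gPBWT). Provides graph construction from a
    reference sequence plus nonoverlapping variants or from GFA, thread
    validation and conversion, incremental and batch index construction,
    exact thread extraction, and subhaplotype occurrence counting in time
    proportional to the query length. Includes run-length-compressed
    rank/insert arrays backing the index, phased-VCF haplotype import with
    splitting of invalid pieces, synthetic haplotype-panel and random-walk
    generators, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    vcfR,
    tibble,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
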