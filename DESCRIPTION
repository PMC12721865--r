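Package: synsieve
Title: Collection and Dereplication of Genomic Neighbourhoods for Synteny Plots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Prepares genomic neighbourhoods for neighbourhood-scale synteny
    plots. The 'collect' step parses a cblaster binary hit table, computes a
    fixed-length span centred on each clustered-hit interval, filters hits
    that are too dispersed or fall on contigs too short to supply the span,
    and writes each surviving neighbourhood as a named GenBank file. The
    'sieve' step dereplicates a folder of GenBank neighbourhoods: proteins
    are compared all-vs-all, reciprocal best hits define a pairwise
    similarity score (the proportion of genes in the smaller neighbourhood
    with a reciprocal best hit in the larger one), and a greedy
    maximum-degree pruning of the resulting similarity graph removes
    neighbourhoods that exceed a user-chosen similarity to any other.
    Diagnostic outputs include an interactive HTML view of the similarity
    graph and a histogram of all non-zero pairwise scores. A synthetic
    neighbourhood generator with controlled homology structure supports
    fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    igraph,
    jsonlite,
    ggplot2,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
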