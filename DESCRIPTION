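Package: metamobilome
Title: Classification and Resistance-Gene Statistics for Circularized
    Mobile Genetic Elements from Contaminated-Subsurface Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for meta-mobilome studies of circularized DNA
    elements assembled from environmental metagenomes. Screens out assembly
    artifacts (organellar fragments, tandem-repeat circularizations) and
    dereplicates elements within contamination strata; classifies each
    element as viral, plasmid, unclassified mobile genetic element, or
    cryptic via a four-tier evidence cascade; predicts hosts by gene-taxonomy
    majority vote and CRISPR-spacer filtering; and quantifies heavy-metal
    resistance gene (HMRG) content: per-megabase and per-CDS densities,
    per-gene Fisher-exact enrichment with Benjamini-Hochberg correction,
    circular gene-neighborhood clustering statistics, co-occurrence matrices,
    and association with conjugative elements. A synthetic-mobilome generator
    with a ground-truth manifest makes every stage testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
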