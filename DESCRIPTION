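Package: nlrome
Title: Genome-Wide NLR Gene Family Identification and Evolutionary Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for genome-wide analysis of plant NBS-LRR (NLR) disease
    resistance gene families in Triticeae genomes. Identifies NLR genes from
    domain-hit evidence, classifies subclasses (CNL/TNL/RNL) and domain
    architectures including integrated domains, profiles the five conserved
    NB-ARC motifs, detects physical gene clusters on chromosomes, re-implements
    MCScanX-style collinear block chaining and duplicate-gene classification,
    and reconciles NLR gene trees with a species tree to account for ancestral
    gene lineages, duplications and losses. A seeded synthetic-genome generator
    provides ground-truthed inputs for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
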