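Package: magtraits
Title: Rule-Based Metabolic Trait Calling for Metagenome-Assembled Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers binary metabolic traits (pathway and enzyme-complex
    presence/absence) for metagenome-assembled genomes (MAGs) from gene
    annotation tables, using a declarative rulebook of diagnostic genes and
    multi-subunit complex completeness thresholds. Includes CheckM-style
    quality filtering, subgroup-level three-state trait summaries,
    mutual-exclusivity co-occurrence screening, hierarchical clustering of
    presence/absence profiles, and a synthetic-data generator that simulates
    genome incompleteness (gene dropout) and contamination (foreign gene
    injection) so trait recovery can be benchmarked against planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pheatmap,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
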