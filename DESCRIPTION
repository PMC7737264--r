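Package: areatax
Title: Area-Taxonomy Quality Assurance for Biomedical Ontologies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Derives area taxonomies and subtaxonomies (abstraction networks
    that partition an ontology hierarchy by exact lateral-relationship-type
    sets) and uses them for quality assurance targeted at missing lateral
    relationships. Flags anomalously large top areas, prioritizes top-area
    concepts by longest-path hierarchical level with a lower/higher-indexed
    half split, evaluates audit findings with two-tailed Fisher's exact
    tests and per-level error tables, classifies descendants of repaired
    concepts and propagates confirmed repairs. Includes readers for a native
    tab-separated triple format and SNOMED CT RF2 snapshot subsets, a
    synthetic-hierarchy generator with planted level-dependent omission
    errors for end-to-end validation, Graphviz DOT export, and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
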