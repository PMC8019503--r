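Package: dqrgen
Title: Automatic Data Quality Rules from openEHR Archetypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Generates executable data quality rules (DQRs) for
    archetype-based clinical data repositories. Parses a pragmatic subset of
    the openEHR Archetype Definition Language (ADL 1.4), extracts and
    normalizes node-level quality constraints (existence, occurrences,
    cardinality, value ranges, value sets, terminology codes, units),
    classifies them against Kahn's harmonized data-quality framework,
    instantiates SQL rule templates through a declarative
    archetype-to-relational mapping, executes the rules on an embedded
    SQLite database (or CSV tables), and evaluates rule-set coverage
    against a reference rule set via a two-aspect agreement procedure.
    Includes a seeded synthetic-data generator that emits archetypes,
    mappings and relational tables with labeled injected defects for
    end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    DBI,
    RSQLite,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
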