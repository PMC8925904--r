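Package: hedlite
Title: Hierarchical Event Descriptor Annotation for BIDS Event Files
Version: 0.9.0
Authors@R:
    person("hedlite", "maintainers", email = "hedlite@example.org",
           role = c("aut", "cre"))
Description: A compact implementation of third-generation Hierarchical Event
    Descriptor (HED) annotation machinery for neuroimaging event streams:
    a hierarchical controlled vocabulary with unique term names and
    short/long-form expansion, a parser and serializer for nested
    parenthesized HED annotation strings, named definitions with Def and
    Def-expand references, assembly of per-event annotations from BIDS
    events.tsv tables and JSON sidecars (including the inheritance
    principle), Onset/Offset temporal scope resolution into event processes
    with event-context insertion, extraction of experimental design matrices
    from Condition-variable definitions, conversion of by-trial event tables
    into by-event form, and a synthetic generator for face-perception style
    MEEG sessions with a 3x3 factorial design. Ships a mini vocabulary and a
    reconstructed face-perception fixture dataset for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
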