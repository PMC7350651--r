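Package: isotrace
Title: Analysis and Pathway-Map Visualization of Stable Isotope Tracing Data
Version: 0.1.0
Authors@R: person("Avery", "Quinn", email = "avery.quinn@example.org",
    role = c("aut", "cre"))
Description: A scriptable toolkit for single-tracer GC-MS stable isotope
    tracing data. Corrects baseline-corrected isotopologue counts for
    natural isotope abundance using elemental-formula-derived correction
    matrices, computes mass isotopomer distributions, mole percent
    enrichment and normalized abundances across sample groups, and renders
    deterministic publication-quality figures, optionally overlaid on
    Escher metabolic-map JSON via BiGG identifiers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    optparse
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
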