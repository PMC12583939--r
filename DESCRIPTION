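Package: soagraph
Title: Graph-Based Clinical Trial Schedules of Activities with FHIR R5 Interchange
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models clinical study schedules of activities (SoA) as directed
    property graphs: interactions (visits, contacts) and activities are nodes,
    transitions between them are edges carrying timing delays, permitted
    windows, and conditional rules. Provides structural validation, expansion
    of protocol-implied paths (withdrawal routes, unscheduled-visit routes),
    a rule engine for a human-readable conditional-scheduling syntax, a
    path-timing engine with a planned-timing consistency check, and a
    per-subject schedule walker supporting repeats, treatment cycles,
    unscheduled visits, and withdrawal. SoA graphs convert losslessly to and
    from FHIR R5 PlanDefinition resources via the soaTimePoint and
    soaTransition extensions, and read/write tabular SoA matrices (CSV),
    a native JSON document format, and GraphML for visual editing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    stats,
    tools,
    utils
Suggests:
    igraph,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
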