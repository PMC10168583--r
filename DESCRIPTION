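Package: complexfix
Title: Detect, Repair and Deduplicate Recursive Molecular Complexes in BioPAX
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditing molecular complexes in BioPAX Level 3
    pathway exports. Complexes are classified against the flat-composition
    rule (a complex may not contain another complex unless that inner
    complex is a black box), invalid recursive composition trees are
    flattened with globally correct stoichiometric coefficients propagated
    along every composition path, and redundant complexes -- distinct
    records sharing the same flattened components, coefficients and
    cellular location -- are grouped into maximal cliques. Includes readers
    and writers for BioPAX RDF/XML and Turtle, a synthetic fixture
    generator with ground truth for testing, and tabular before/after
    summary reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
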