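Package: podoconsensus
Title: Evidence-Consensus Scoring of National Podoconiosis Status
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements a weighted evidence-consensus framework for
    classifying every country's podoconiosis (non-filarial elephantiasis)
    status on a -100 to +100 scale with graded certainty bands. Countries
    with published case reports are scored on four evidence categories
    (health-organisation agreement, contemporariness, diagnostic rigour,
    deduplicated case counts; maximum 15); countries without reports are
    scored on a three-component absence index built from misdiagnosis
    propensity, the Healthcare Access and Quality Index and the
    Socio-Demographic Index (maximum 3). Includes delimited-text readers
    and writers for the evidence tables, band summaries and continental
    breakdowns, a GeoJSON choropleth export, a synthetic evidence-landscape
    generator with an independent scoring oracle, and a packaged fixture
    encoding the published 27-country national results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
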