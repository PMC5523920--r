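Package: raclnet
Title: Capacitated Set-Covering Placement of Diagnostic Laboratories and
    Point-of-Care Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scenario planning for tiered diagnostic laboratory networks.
    Clusters health facilities within a fixed radius, calibrates a linear
    drive-time model from sampled (distance, drive time) pairs, solves a
    capacitated set-covering location-allocation that selects the minimum
    number of laboratories covering every facility cluster within a
    travel-time threshold (with point-of-care fallback for unreachable
    clusters), and translates each selected laboratory's allocated daily
    test volume into service tier, analyser platform configuration,
    instrument quantity and bench-space requirements. Includes an exact
    branch-and-bound solver validated against exhaustive enumeration, a
    scalable greedy heuristic, a seeded synthetic network generator, and
    GeoJSON/KML map-layer output.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    geosphere,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
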