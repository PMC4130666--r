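Package: meiocross
Title: Tetrad Analysis and Crossover Interference Statistics for Meiosis
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying meiotic crossover number, position and
    interference from pollen-tetrad fluorescence assays and from cytological
    data. Implements tetrad classification for three linked markers, Perkins
    map distances, the NPD ratio against the Papazian no-interference
    expectation, the Malkova interference ratio, the coefficient of
    coincidence, a Monte-Carlo uniformity test for spacing of recombination
    foci within clusters, chiasma scoring from metaphase I bivalent
    configurations, and a gamma-renewal crossover simulator with tunable
    interference that generates all three data kinds for validation and
    power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
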