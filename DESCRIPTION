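Package: phbflux
Title: Flux Balance Analysis of Poly-(3-Hydroxybutyrate) Production in
    Escherichia coli Central Metabolism
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A curated stoichiometric model of Escherichia coli central
    carbon metabolism extended with the poly-(3-hydroxybutyrate) (P3HB)
    synthesis pathway and the non-oxidative glycolysis (NOG)
    phosphoketolase knock-in.  Provides flux balance analysis and flux
    variability analysis on a simplex linear-programming backend,
    theoretical maximum production rates and carbon yields for glucose,
    xylose and glycerol scenarios, carbon-yield arithmetic for measured
    titers, elemental-balance validation of stoichiometric models, a
    plain-text model interchange format with optional SBML import, and a
    generator of small mass-balanced test networks with planted optima.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    xml2
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
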