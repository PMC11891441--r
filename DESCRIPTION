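Package: bofkit
Title: Build Mass- and Charge-Balanced Biomass Objective Functions for
    Genome-Scale Metabolic Models
Version: 0.1.0
Authors@R:
    person("bofkit", "developers", email = "bofkit@example.org", role = c("aut", "cre"))
Description: Converts biomass composition measurements (mass fractions,
    molar amounts or mole fractions in user units) into a structured,
    mass- and charge-balanced biomass objective function (BOF) with up to
    three levels of pseudo-reactions and pseudo-metabolites, and inserts
    it into -- or removes it from -- a genome-scale metabolic model.
    Reads and writes SBML (Level 3 + FBC v2) and COBRA-JSON models,
    parses a structured composition workbook (directory of TSV sheets or
    an XLSX file), normalizes the recovered mass to 1 g dry weight,
    computes elemental formulas and charges of the generated
    pseudo-metabolites, validates elemental and charge balance, and
    checks growth feasibility by flux balance analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    optparse,
    readxl,
    testthat (>= 3.0.0),
    withr,
    zip
Config/testthat/edition: 3
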