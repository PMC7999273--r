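Package: diazoflux
Title: Constraint-Based Analysis of Two-Cell Diazotrophic Cyanobacterial
    Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building and interrogating two-cell (vegetative cell
    plus heterocyst) stoichiometric models of filamentous nitrogen-fixing
    cyanobacteria. Provides readers and writers for SBML (Level 3 'fbc'),
    a tabular reaction dialect and JSON; construction of two
    super-compartment diazotrophic models from a single-cell template with
    cell-specific deletions and inter-cell metabolite exchanges; flux
    balance analysis, parsimonious FBA and flux variability analysis on a
    built-in bounded-variable simplex solver; scenario analysis of
    heterocyst ATP/NAD(P)H generating schemes; and OptForce-style strain
    design (MUST set identification, bi-level intervention search solved
    as a single-level MILP via LP duality, integer-cut enumeration of
    alternative strategies). A deterministic synthetic two-cell network
    with hand-verifiable optima is included so every analysis is testable
    without external model files.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
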