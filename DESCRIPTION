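Package: minprec
Title: Enumeration of Minimal Stoichiometric Precursor Sets in Metabolic
    Networks
Version: 0.1.0
Authors@R:
    person("minprec", "maintainers", email = "minprec@example.org",
           role = c("aut", "cre"))
Description: Decides and exhaustively enumerates all minimal stoichiometric
    precursor sets (minimal nutrient/source-compound sets) of target
    metabolites in a metabolic network, under an accumulation,
    steady-state, or machinery-duplicating flux model. The core engine
    iteratively solves mixed-integer linear programs with exclusion cuts;
    an independent combinatorial enumerator over minimal topological
    factories of the many-to-one transformed hypergraph and a brute-force
    subset oracle provide cross-checks. Includes a plain-text reaction-list
    and basic SBML reader, stoichiometric cut-set membership tests, and a
    command-line front end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    xml2
Suggests:
    boot,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
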