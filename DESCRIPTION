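Package: pathcascade
Title: Design and Ranking of Multi-Enzyme Biosynthesis Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing multi-step enzymatic synthesis routes in
    reaction-pair (arc) networks built from KEGG-style reaction data.
    Reconstructs a directed metabolic network with curated exclusion
    filters and thermodynamics-based reversibility assignment, enumerates
    candidate pathways to a target metabolite with a mixed-integer linear
    program that searches from arbitrary start metabolites and excludes
    previously found solutions, and filters, ranks and reports candidates
    using seven biochemical criteria (pathway length, basis-metabolite
    start, Gibbs energy profile, kinetic traps, heterologous enzymes,
    cofactor demand) with per-candidate thermodynamic profiles, reactant
    balances, side-reaction lists and SBML output. Includes an exact
    branch-and-bound solver for the small mixed-integer programs involved,
    deterministic synthetic-network generators and a brute-force pathway
    oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    xml2,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
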