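Package: cgpep
Title: Coarse-Grained Molecular Dynamics Screening of Short Peptide Self-Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for studying the self-assembly of 1-3 residue
    peptides with MARTINI-style coarse-grained models. Bundles bead-type and
    nonbonded interaction tables for the 2.1, 2.2 and 3 force-field generations
    (with per-entry provenance flags), a topology builder for nine amino acids,
    a minimal NPT molecular-dynamics engine (shifted Lennard-Jones, reaction-field
    electrostatics, V-rescale thermostat, Berendsen barostat, SHAKE constraints),
    and the quantitative screening metrics used in the field: SASA-based
    aggregation propensity, side-chain radial distribution functions,
    constraint-corrected group temperatures, supramolecular morphology
    classification and tube-fraction statistics, together with a screening
    orchestrator that produces phase-diagram tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
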