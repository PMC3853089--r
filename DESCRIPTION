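Package: wetcore
Title: Topology of Buried Water in Protein-Protein Interfaces
Version: 0.1.0
Authors@R:
    person("Wetcore", "Developers", email = "wetcore@example.org",
           role = c("aut", "cre"))
Description: Quantifies how interfacial water is organized in protein-protein
    complexes. Reads crystal structures (PDB/mmCIF), iteratively removes
    bulk-exposed water, builds a Voronoi-plus-distance atomic contact graph,
    extracts the protein-water-protein tripartite interface, and computes
    burial levels, the relative water burial level (rWBL), the Gini
    coefficient of the water-contact distribution, wetness and interface
    area (dSASA). Includes tools to compare a wild-type/mutant structure
    pair (Kabsch superposition, per-residue RMSD, water reappearance,
    normalized B-factor change by interface region and burial depth) and a
    synthetic slab-dimer generator with planted ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
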