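Package: TemplateSites
Title: Template-Based Prediction of Protein-Ligand Binding Sites
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds a quality-controlled database of ligand-bound protein
    chain templates from PDB-format files (experiment-method, resolution,
    chain-length, ligand-size and complex-stability filters, with homology
    and chain-length indexes) and predicts ranked ligand-binding sites on
    query chains by combinatorial-extension structural alignment against
    the templates, mapping of template ligands into the query frame, and
    consensus clustering of mapped ligand centers.  Includes residue-level
    evaluation (center-hit accuracy and Matthews correlation coefficient)
    and a deterministic synthetic-structure generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
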