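Package: mapfp
Title: MinHashed Atom-Pair Molecular Fingerprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes MinHashed atom-pair (MAP) molecular fingerprints from
    SMILES by combining circular-substructure SMILES shingles with topological
    atom-pair distances, together with modulo-folded variants. Includes an LSH
    forest for approximate nearest-neighbor similarity search, a peptide
    virtual-screening benchmark (scrambled and point-mutated decoy sets with
    optional BLAST labelling), early-recognition screening metrics (AUC,
    enrichment factors, RIE, BEDROC), and nearest-neighbor
    indistinguishability analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ChemmineR,
    ChemmineOB,
    Biostrings,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
SystemRequirements: OpenBabel (via ChemmineOB); optionally NCBI BLAST+
    (blastp) for benchmark labelling.
Config/testthat/edition: 3
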