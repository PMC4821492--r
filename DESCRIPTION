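Package: ssefold
Title: Low-Resolution Protein Topology Search by Monte Carlo Assembly of
    Secondary Structure Elements
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: De novo low-resolution protein topology search: idealized
    secondary structure elements (SSEs) built from canonical dihedral
    angles are assembled in space by a staged Monte Carlo Metropolis
    search under a weighted sum of knowledge-based (inverse-Boltzmann)
    and distance-restraint scoring terms.  Includes the surrounding
    model-selection machinery (completeness filtering, score-stratified
    k-medoids clustering with medoid extraction, enrichment) and
    evaluation metrics against a reference structure (GDT_TS, RMSD100,
    contact order, ensemble summaries), plus readers for FASTA, PDB,
    PSIPRED ss2, CASP RR contact and tabular NOE/cross-link restraint
    formats and seed-deterministic synthetic fixture generators.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    bio3d,
    cluster,
    seqinr,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
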