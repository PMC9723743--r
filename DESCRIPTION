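Package: nullassembly
Title: Null-Model Analysis of Host-Associated Microbiome Assembly
Version: 0.1.0
Authors@R:
    person("nullassembly", "developers", email = "nullassembly@example.org", role = c("aut", "cre"))
Description: Tools to dissect selective versus neutral (lottery) assembly of
    low-richness host-associated bacterial communities sampled together with
    their environmental source communities. Provides readers and validators
    for OTU count tables, sample metadata, phylogenies and functional
    annotation maps; preprocessing (noise floor, organelle removal,
    rarefaction, curation of nested function labels); two bespoke
    randomisation procedures (abundance-proportional lottery reassembly from
    the source community, and a station-constrained quasiswap preserving row
    and column totals and matrix fill); taxonomic, functional and
    phylogenetic diversity indices including the checkerboard C-score; the
    Sloan neutral community model with Efron's pseudo R-squared; constrained
    correspondence analysis with PCNM spatial/phylogenetic eigenvectors,
    forward selection, VIF filtering and two-set variation partitioning; and
    a fully parameterised synthetic-data generator with known ground truth
    for selection, competition and neutrality.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
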