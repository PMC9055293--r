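Package: divabc
Title: Divergence-Scenario ABC and Selection Scans for Two-Population SNP Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing speciation scenarios between two hybridizing
    populations from RAD-seq style SNP data. Provides an event-driven
    two-deme coalescent simulator with epoch-wise migration under five
    divergence scenarios (isolation, isolation with migration, old
    migration, secondary contact, and decreasing migration), the classical
    two-population summary statistics (Tajima's D, Hudson and
    Weir-Cockerham F_ST, shared/fixed/private allele proportions, joint
    site frequency spectrum), approximate Bayesian computation with
    neural-network model choice and regression-adjusted parameter
    estimation, and a candidate-gene screen combining principal-component
    Mahalanobis outlier detection with Nei-Gojobori Ka/Ks estimates on
    orthologous coding sequences. A synthetic-data generator emulates the
    statistical structure of two-species RAD-seq SNP matrices so the whole
    pipeline can be exercised end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nnet,
    MASS,
    Rcpp,
    jsonlite,
    vcfR,
    Biostrings
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
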