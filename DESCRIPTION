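Package: tipdater
Title: Bayesian Tip-Date Estimation for Serially Sampled Ancient Mitogenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Molecular-clock dating of ancient specimens from serially sampled
    mitochondrial genome alignments. Implements Felsenstein pruning under an
    HKY+G4 substitution model, the heterochronous constant-population-size
    coalescent (simulator and density), a Metropolis-Hastings sampler that
    treats unknown specimen ages as parameters (both a joint and a two-stage
    individually-dated procedure), F84 pairwise distances and clade-level
    nucleotide diversity, and ancient-DNA consensus curation rules
    (read filtering, depth and multiallelic masking, majority base calls,
    terminal deamination profiles). Includes a synthetic-data generator for
    coalescent genealogies, HKY+G4 alignments and degraded ancient-DNA read
    sets so that every stage is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
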