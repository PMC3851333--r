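Package: dicerscan
Title: Prediction of Dicer Cleavage Sites on pre-miRNA Hairpins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts human Dicer cleavage sites on pre-microRNA hairpins
    from sequence and secondary-structure context. Candidate cut positions
    are encoded as fixed-width windows over the stem duplex (nucleotide
    composition, one-hot sequence profiles, and one-hot structure profiles
    with an explicit loop/bulge state) and classified with a radial-basis
    support vector machine tuned by family-grouped five-fold
    cross-validation. Includes whole-hairpin scanning with top-k site
    ranking, position-shift-error assessment, classification of the effect
    of single-nucleotide variants on cleavage sites, and a seeded synthetic
    hairpin generator for end-to-end benchmarking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    Biostrings,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
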