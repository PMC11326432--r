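Package: toothpos
Title: Tooth Complexity and Dentition Position in Non-Mammalian Synapsids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative phylogenetic analysis of tooth morphological
    complexity and the anteroposterior position of the dentition in the
    cranium, built for fossil (non-ultrametric) trees. Provides majority-rule
    consensus trees with branch lengths, age-based tip grafting, landmark
    projection onto the cranial midline with scale calibration, an ordinal
    five-level tooth-complexity classifier, phylogenetic generalized least
    squares with Pagel's lambda estimated by maximum likelihood, ordered
    (Sankoff) parsimony ancestral-state reconstruction with exhaustive
    most-parsimonious-reconstruction enumeration and acquisition/loss
    counting, squared-change parsimony for continuous characters, a
    synthetic-data generator with the statistical structure the analysis
    assumes, and a pipeline that runs the whole study from trees and
    measurement tables to regression and ancestral-state reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
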