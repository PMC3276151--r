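Package: lobeqtl
Title: Outline Morphometrics and QTL Mapping of Drosophila Posterior Lobe Shape
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A simulation-backed pipeline for the genetic dissection of a
    landmark-free shape trait: elliptic Fourier outline morphometrics (shape
    principal components and centroid-based size metrics), interval and
    composite interval mapping by multiple imputation in F2 and advanced
    intercross (AIL) populations with Drosophila female-only recombination,
    selective genotyping with stratified permutation thresholds, multiple-QTL
    model fitting with epistasis and drop-one variance decomposition, 2-LOD
    support intervals, and a candidate-locus LOD-sum resampling test. A
    synthetic-data module simulates both the crosses and the genital-arch
    lobe outlines so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, tools, yaml
Suggests: testthat (>= 3.0.0), optparse, jsonlite, knitr, rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
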