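Package: galdose
Title: Gene-Dosage Fitness and Epistasis Analysis for the Yeast GAL Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools to quantify the fitness consequences of combinatorial
    gene-dosage reduction in the Saccharomyces cerevisiae galactose
    utilization network. Simulates two-strain competition experiments
    observed by flow cytometry (log-normal fluorescence, exponential
    log-odds growth dynamics, debris contamination), reproduces the
    FSC-SSC density gate, classifies query versus reference events,
    estimates reference-normalized expression and wild-type-normalized
    relative fitness with replicate standard errors, averages per-gene
    dosage effects over matched genetic backgrounds, decomposes overall
    and net epistatic deviations on the 2^4 dosage lattice with
    delta-method error propagation and Holm-Bonferroni-controlled Z-tests,
    and fits a linear expression-by-galactose dose-response model with a
    saturation diagnostic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
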