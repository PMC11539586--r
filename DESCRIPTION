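Package: dnamixr
Title: Accuracy of Forensic DNA Mixture Interpretation Across Groups of
    Differing Genetic Diversity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation pipeline for studying how the accuracy of
    semi-continuous (presence/absence) forensic DNA mixture interpretation
    varies with the genetic diversity of the contributors' group and with
    mis-specification of the reference allele-frequency distribution.
    Provides readers and quality control for STR allele-frequency tables,
    expected-heterozygosity and Weir-Cockerham F_ST estimators with an
    F_ST-threshold panel-pruning algorithm, Hardy-Weinberg genotype and
    mixture simulation, a dropout-aware likelihood-ratio engine summing
    over one unknown contributor, false-positive-rate and power studies
    with correlation analyses, and a synthetic allele-frequency panel
    generator with controlled diversity and Balding-Nichols divergence.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
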