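Package: cfdnaflux
Title: Mass-Balance Accounting of Plasma Cell-Free DNA Against Cellular Turnover
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts cell-type-specific cellular turnover rates into the
    plasma cell-free DNA (cfDNA) concentrations that would be observed if all
    DNA of dying cells reached the bloodstream, compares these "potential"
    concentrations with measured cfDNA levels from methylome deconvolution,
    and estimates the fraction of dying-cell DNA captured as plasma cfDNA.
    All quantities carry multiplicative (lognormal) uncertainty; propagation
    uses the product shape rule for products and ratios and seeded bootstrap
    resampling for sums and for the ultrashort-fragment adjustment of the
    total cfDNA concentration. Includes a synthetic-cohort generator for
    parameter-recovery checks and a reconstructed reference cell-type table.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
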