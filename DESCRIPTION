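Package: difbias
Title: Measurement Bias from Differential Item Functioning in Partial
    Credit Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation machinery and decision rules for studying the
    consequences of differential item functioning (DIF) in short composite
    measurement scales analysed with the partial credit model.  Generates
    polytomous item responses for two groups under uniform, balanced
    non-uniform and unbalanced non-uniform DIF, estimates latent group
    differences with a latent-regression partial credit model fitted by
    marginal maximum likelihood (Gauss-Hermite quadrature), quantifies the
    measurement bias that arises when DIF is ignored across a factorial
    design, and encodes triage rules that separate meaningful from
    ignorable DIF.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
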