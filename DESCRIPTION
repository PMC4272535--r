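Package: stmc
Title: Pseudo-3D Spatio-Temporal Statistical Model Checking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Validates stochastic spatial computational models against formal
    spatio-temporal specifications. Simulation traces of pseudo-3D systems
    (2D grids carrying density values) are analysed by parameterised image
    processing to detect spatial patterns (regions) and clusters of patterns,
    each characterised by eleven spatial measures. Traces are serialised in
    the Spatial Temporal Markup Language (STML, an XML dialect with a shipped
    schema) and evaluated against Probabilistic Bounded Linear Spatial
    Temporal Logic (PBLSTL) statements using five approximate statistical
    model-checking algorithms: Wald sequential probability ratio test,
    Chernoff-Hoeffding estimation, Bayesian hypothesis testing, Bayesian
    estimation, and probabilistic black-box checking with exact binomial
    p-values. Includes synthetic generators emulating sector patterning in
    growing bacterial colonies and chemotactic aggregation of cells.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    cluster,
    stats,
    utils,
    xml2
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
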