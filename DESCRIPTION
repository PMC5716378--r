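Package: wntgsa
Title: Global Sensitivity Analysis of Wnt-Pathway Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Variance-based (Sobol pick-freeze family) and density-based
    (Csiszar f-divergence, Hilbert-Schmidt independence criterion)
    global sensitivity indices for gene-expression studies of the Wnt
    signalling pathway. Implements a static normal-versus-tumor bootstrap
    experiment and time-course experiments on fold changes and on
    deviations in fold changes between consecutive time points, the
    latter motivated by the Weber-Fechner psychophysical law. Includes
    synthetic-data generators emulating the statistical structure of the
    expression datasets, tidy result tables, ggplot2 visualisations and
    reproducible run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
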