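Package: olfadapt
Title: Efficient-Coding Models of Olfactory Receptor Abundances
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for computing information-maximizing distributions of
    olfactory sensory neurons (OSNs) across receptor types. Given a
    receptor-by-odorant sensing matrix, Gaussian odor-environment
    statistics, per-receptor noise variances and a total neuron budget,
    the package solves the constrained mutual-information maximization on
    the simplex of receptor abundances (a correlated-channel water-filling
    problem), integrates an experience-dependent birth/death dynamics that
    converges to the same optimum, generates synthetic odor environments
    and sensing matrices with controlled correlation and tuning width, and
    scripts in-silico experiments on environment change, tuning width,
    subsampling robustness, and odor exposure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
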