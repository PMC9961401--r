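Package: myrmspat
Title: Spatial Pattern and Infestation Analysis of Myrmica Ant Nests
    Hosting Social Parasites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the micro-spatial distribution of Myrmica
    ant nests and their infestation by social parasites such as Maculinea
    butterfly and Microdon fly larvae. Provides marked point pattern
    containers for two-season nest surveys, Monte Carlo quadrat tests of
    complete spatial randomness with variance-mean ratios at multiple grid
    scales, join-count statistics over distance-band neighbourhoods with
    random-labelling permutation nulls, kernel-smoothed density surfaces,
    infestation-rate tabulation with chi-square season contrasts, and
    AIC-based logistic model selection and averaging for parasite
    occurrence. A Thomas cluster process generator produces synthetic
    two-season marked nest patterns with the survey's statistical structure
    so every analysis stage runs without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    mgcv,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
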