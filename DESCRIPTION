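Package: ecodriver
Title: Predicting Ecosystem Function from Microbial Community Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Machine-learning toolkit for regressing a continuous ecosystem
    function (such as dissolved organic carbon from litter decomposition) on
    microbial community profiles, and for selecting a consensus set of driver
    taxa. Implements a feed-forward neural-network regressor with
    gradient-based signed feature importance and bootstrap ranking, a random
    forest counterpart, Dufrene-Legendre indicator taxa analysis with a
    permutation confidence procedure, consensus feature selection with a
    Monte Carlo random-overlap null, replicate-group-aware data splitting,
    rarefaction, sample-size sensitivity analysis, and gradient-based
    in-silico community design. A synthetic community generator reproduces
    the sparse fixed-depth count structure of rarefied 16S profiles for
    testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    ranger,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
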