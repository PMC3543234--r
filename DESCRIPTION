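Package: pollenseed
Title: Pollen Versus Seed Gene Flow from Nuclear and Organelle Markers
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative analysis of biparentally inherited (nuclear
    microsatellite) and maternally inherited (organelle haplotype)
    population structure in plants. Implements Weir-Cockerham
    F-statistics with locus jackknife errors and permutation tests,
    distance-based AMOVA, Loiselle kinship coefficients with the Sp
    statistic for spatial genetic structure, Nei's haplotype G_ST and
    diversity, the Ennos pollen-to-seed migration ratio, the
    Hamilton-Miller expected-maternal-FST test, the Brookfield null
    allele estimator, and a forward-time simulator of mixed-mating
    metapopulations with decoupled pollen and seed dispersal.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    ape,
    geosphere,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
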