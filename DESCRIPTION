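Package: amendr
Title: Community Response and Carbon Budget Modelling for In Situ
    Organic-Matter Amendment Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing in situ microbial colonization experiments in
    deep aquifers that include a pulsed organic-matter amendment. Provides a
    seeded Dirichlet-multinomial simulator for 16S OTU count tables with
    substrate-linked effects, perturbation blooms and sequencing controls; the
    standard amplicon filtering steps (singleton removal, dataset-wide
    relative-abundance thresholding, negative-control contaminant removal) with
    relative-abundance and fourth-root transforms and alpha-diversity
    estimators (Shannon, Chao1); from-first-principles community statistics
    (Bray-Curtis dissimilarity, non-metric multidimensional scaling with
    Kruskal stress-1, permutation ANOSIM, SIMPER decomposition) plus classical
    one-way ANOVA and variance-ratio tests; and a plane-source Fickian
    diffusion model of a nutrient pulse in a well bore with a sponge
    carbon/nitrogen budget and per-cell carbon oxidation rate estimators tied
    to an incubation timetable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
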