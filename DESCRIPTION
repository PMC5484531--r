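Package: epidil
Title: Epistasis Among Conspecific Introgressions from Double-Introgression-Line Fertility Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers epistatic interactions among conspecific chromosomal
    introgressions from the fertility phenotypes of double-introgression
    lines (DILs). For each DIL the package fits additive and multiplicative
    relative-fitness models with a single epistasis parameter, selects
    models by BIC, tests epistasis by likelihood-ratio against the best
    non-epistatic null, and controls the false discovery rate within each
    phenotype. Significant interactions are summarised as a genetic
    interaction network with per-edge classification of the possible
    Dobzhansky-Muller incompatibility (DMI) architecture. A synthetic
    phenotype generator with known ground-truth epistasis makes every stage
    testable without greenhouse data, and a snowball simulator quantifies
    the accumulation and saturation of pairwise DMIs between diverging
    lineages.
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
    igraph,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
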