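Package: sporetrade
Title: Offspring Size, Spore Output and Body-Size Scaling in Arbuscular
    Mycorrhizal Fungi
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Comparative analysis of offspring (spore) size in arbuscular
    mycorrhizal fungi. Converts published spore diameter-range descriptions to
    volumes and masses, compares offspring-size distributions across taxa,
    estimates phylogenetic signal (Pagel's lambda) by maximum likelihood with a
    likelihood-ratio test, computes Felsenstein's phylogenetically independent
    contrasts, and fits the Smith-Fretwell offspring size-number trade-off and
    reproductive allometry by standardized major axis regression with tests
    against inverse proportionality (slope -1). Includes converters from
    greenhouse colonization measurements (root ergosterol, soil hyphal length,
    spore density) to common biomass units, a fully seeded synthetic-data
    generator with known ground truth, and an end-to-end pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    phytools,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
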