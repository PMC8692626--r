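Package: overwintr
Title: Diapause Capability Analysis for Calanus Copepods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the overwintering (diapause) capability of
    Calanus finmarchicus from individual biometrics, depth-stratified net
    catches and CTD temperature profiles. Converts lipid sac area to wax-ester
    carbon, partitions total body carbon into lipid reserve and structural
    mass, models temperature-dependent diapause respiration with an Arrhenius
    factor, derives per-individual diapause durations and classifies
    overwinter capability, and scales the classification to depth-integrated
    population abundances. Includes a seeded synthetic-data generator that
    emulates station hydrography, stage-structured vertical distributions and
    lipid-fullness distributions so that every pipeline stage can be tested
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    ggplot2,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
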