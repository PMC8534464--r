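Package: osmokin
Title: Mass-Transfer Kinetics of Osmotic Dehydration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing osmotic-dehydration experiments on fruit:
    derivation of water loss, solid gain and weight reduction from raw
    mass/moisture measurements; forward evaluation and least-squares fitting
    of the Peleg, Azuara, Page and Crank (sphere diffusion) kinetic models,
    with equilibrium values and effective diffusivities; model comparison by
    R-squared and RMSE; CIELAB colour change and fresh-weight-basis quality
    corrections; and a seeded synthetic-data generator for end-to-end
    parameter-recovery studies.
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
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
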