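Package: catchrt
Title: Watershed-Scale Hydro-Biogeochemical Reactive Transport on Bucket Hydrology
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A parsimonious watershed-scale reactive transport simulator that
    couples a three-zone bucket hydrology (snowpack, transient surface zone,
    shallow soil zone, deep groundwater zone) with multi-component solute
    transport, equilibrium speciation by mass action, and kinetic
    biogeochemical reactions (transition-state-theory mineral dissolution,
    Monod and inhibition microbial kinetics, with temperature, soil-moisture
    and water-table rate modifiers). Includes a standard HBV-type bucket
    hydrology model, readers for HBV-light-style output, a CrunchFlow-style
    geochemical database parser, ready-to-run carbon and nitrogen example
    networks, a synthetic humid-continental climate generator, and
    concentration-discharge (C-Q) analysis utilities.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
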