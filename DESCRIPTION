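Package: forageweb
Title: Bioeconomic Management of a Forage Fish Food Web
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A coupled ecological-economic model of a California Current
    food web (northern anchovy, Pacific sardine, California halibut and
    Brown Pelican) for evaluating ecosystem-based fisheries management.
    Delay-differential population dynamics with environmentally forced
    recruitment, Type-II multispecies predation, prey-dependent seabird
    vital rates, quadratic-profit fisheries with an open-access closure,
    stylized harvest control rules, and numerical optimal control of
    fishing effort under alternative management regimes, optionally
    subject to a floor on the seabird population. Post-processing
    utilities compute net-present-value accounting, long-run seabird
    gains, elasticities and regime comparison tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
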