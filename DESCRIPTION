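Package: forestmf
Title: Three-Dimensional Multifunctionality Analysis for Multipurpose Forest Management
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes multidiversity, ecosystem multifunctionality and economic
    multifunctionality for forest stands as effective numbers of taxa or
    functions (Hill-number style, with a correlation correction via the
    tau-profile area under the curve), derives six bio-economic indicators
    from 30-year stand trajectories (net present value, annuity, stumpage
    value, sawn-timber share, investment-corrected profit, and Weibull
    conditional survival), and quantifies net diversity effects and
    synergies or trade-offs among the three dimensions with BCa bootstrap
    inference. Includes a synthetic study-design generator emulating a
    blocked quintet design of pure and enriched European beech stands, so
    the full pipeline is exercisable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    yaml
Suggests:
    boot,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
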