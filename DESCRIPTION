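Package: menufop
Title: Front-of-Package "High-in" Labelling Rules for Restaurant Menu Items
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements Health Canada's mandatory front-of-package (FOP)
    "high-in" labelling regulations (Canada Gazette II, July 2022) as a
    reusable classification engine for restaurant menu items, together with
    a batch analysis pipeline covering exemptions, missing-serving-size
    exclusions, serving-size-banded percent-daily-value thresholds, category
    tabulations, descriptive statistics, and a sensitivity analysis for
    items missing serving sizes. A calibrated synthetic menu generator with
    a closed-form flag-rate oracle supports validation without access to
    proprietary menu databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
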