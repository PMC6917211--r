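Package: cardiocost
Title: Microsimulation of Diet-Attributable Cardiometabolic Disease Costs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates annual cardiometabolic disease (coronary heart disease,
    stroke, and type 2 diabetes) healthcare costs attributable to suboptimal
    intake of ten dietary factors. A person-level cardiovascular
    microsimulation is run in yearly cycles under observed-diet and
    optimal-diet counterfactual scenarios; the cost difference, split into
    acute, chronic (CVD and diabetes), and drug components, is the
    attributable cost. Includes a calibrated synthetic-population generator
    emulating a national health survey of US adults aged 35-85, log-linear
    dose-response relative risks, half-cycle-corrected discounted cost
    accounting, stratified reporting, Monte-Carlo confidence intervals over
    relative-risk uncertainty, and allocation of costs to ultimate
    cost-bearers (households, government, third parties).
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
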