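Package: telehf
Title: Discrete-Event Simulation of Telemonitored Versus Conventional Heart Failure Care
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patient-level stochastic simulation of outpatient and inpatient
    care pathways for chronic heart failure, stratified by NYHA functional
    class, with a cost engine based on Austrian procedure-oriented
    diagnosis-related case groups (LDF): case flat rates with trim points,
    daily intensive-care supplements and individual-medical-procedure
    components. Two care arms are modelled - conventional care and
    telemedical home monitoring with a weekly control cycle - together with
    two financing schemes for the telemonitoring system. Scenario
    configurations are plain YAML files; results are tidy tibbles with
    broom-style tidiers, ggplot2 plotting methods, break-even detection,
    mortality summaries and one-at-a-time sensitivity sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    yaml
Suggests:
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
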