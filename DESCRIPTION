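Package: effshunt
Title: Effective Shunt Fraction and Predictive Validity of Oxygenation Indices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-invasive estimation of the effective shunt fraction from a single
    arterial blood gas, using an oxyhaemoglobin dissociation model with a
    pH/PCO2-shifted P50, the alveolar gas equation, the Fick principle, and a
    numerical inversion of the content-tension relationship. Includes a
    multi-compartment steady-state gas-exchange simulator (pure shunt plus
    ventilation-perfusion heterogeneity), a database-matching method that infers
    the physiological states consistent with one or two blood gases, a synthetic
    ICU weaning-cohort generator, and a predictive-validity pipeline that scores
    effective shunt against the PaO2/FiO2 ratio and the alveolar-arterial
    difference by their ability to predict PaO2 after a change in inspired
    oxygen.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
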