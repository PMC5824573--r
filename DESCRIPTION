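Package: gdmburden
Title: Short-Term Economic Burden Modelling of Gestational Diabetes Mellitus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A probability-tree cost-of-illness model for the last trimester of
    pregnancies complicated by gestational diabetes mellitus (GDM), from a
    national health-service perspective. Computes antenatal outpatient resource
    costs per treatment group, expected inpatient delivery and neonatal-outcome
    costs per case, the GDM versus euglycemia cost difference and the national
    burden; runs one-way (tornado) deterministic and Monte Carlo (beta/gamma)
    probabilistic sensitivity analyses; and implements the hospital-discharge
    database extraction procedure (DRG delivery identification, ICD9 look-back
    GDM flagging, length-of-stay-adjusted tariff costing with percentile
    outlier exclusion) together with a calibrated synthetic discharge-record
    generator so the full extract-then-model loop is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
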