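Package: ndtrace
Title: Case Finding and Rate Estimation for Parkinsonism and Dementia
    from Administrative Health Data
Version: 0.1.0
Authors@R:
    person("Regional", "Epidemiology Tools", email = "ndtrace@example.org",
           role = c("aut", "cre"))
Description: Identifies parkinsonism and dementia cases from linked
    administrative health databases (population registry, outpatient drug
    prescriptions, hospital discharge records, chronic-disease exemptions)
    using a tracer-drug and diagnosis-code adjudication algorithm with a
    psychiatric-confounder exclusion and a disease-free look-back for
    incident cases.  Estimates crude, age-specific and directly
    age-standardized prevalence, incidence and mortality rates (WHO
    2000-2025 and Eurostat ESP 2013 standards) with Wilson and bootstrap
    confidence intervals, Poisson incidence rate ratios, and
    municipality-level rates for disease mapping.  Includes a synthetic
    generator that emulates the four source databases for fully
    reproducible, download-free testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    openssl,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
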