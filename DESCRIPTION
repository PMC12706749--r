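Package: schoolexposure
Title: School-Environment Air and Noise Exposure Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exposure-assessment pipeline for week-long schoolyard monitoring
    campaigns of fine particulate matter (PM2.5), black carbon and environmental
    noise in a tropical city. Calibrates continuous PM2.5 monitors against
    collocated gravimetric filter samples with season-specific correction
    factors, converts one-week campaigns to annual-equivalent concentrations via
    weekly temporal adjustment factors from a fixed-site network, computes
    school-hours equivalent continuous sound levels and the intermittency ratio,
    scores child noise-annoyance surveys into highly-annoyed metrics with a
    binned quadratic exposure-response curve, derives spatial covariates
    (greenness class, road proximity, socioeconomic median split, guideline
    exceedance), and fits generalized additive determinant models with
    thin-plate spline meteorology terms. Includes a synthetic-city generator
    with recorded ground truth so every stage can be validated by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    mgcv,
    readr,
    rlang,
    stats,
    tibble,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
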