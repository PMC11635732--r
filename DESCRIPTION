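Package: foodsecx
Title: Cross-Classified Food Security Measurement for Older Adults
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a multidimensional cross-classification of food
    security for adults aged 60 years and older, combining the 10-item USDA
    Adult Food Security Survey Module (resource constraints) with a 6-item
    physical food security instrument (food-related physical functioning
    limitations) into a single ordered severity status. Includes the
    design-based analysis pipeline used to examine the method against
    NHANES-style complex-survey microdata: multiyear weight construction,
    Taylor-linearized weighted prevalence, Rao-Scott corrected chi-square
    tests, Bonferroni-adjusted design t-tests, survey-weighted logistic and
    linear regression with clustered sandwich variance, factor-analysis
    suitability diagnostics (KMO, Bartlett's sphericity, principal-axis
    extraction), simple per-person HEI-2015 diet-quality scoring, and a
    calibrated synthetic-microdata generator so every stage is testable
    without access to restricted or downloaded survey files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    haven,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
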