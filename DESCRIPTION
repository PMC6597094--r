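Package: fcatools
Title: Floating Catchment Area Accessibility Methods with Proportional
    Allocation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes spatial accessibility to services (for example, family
    physicians) with the family of Floating Catchment Area (FCA) methods:
    the classic two-step method (2SFCA), its enhanced stepwise-impedance
    variant (E2SFCA), the three-step method with selection weights (3SFCA),
    the modified method with squared impedance (M2SFCA), and a balanced
    variant that allocates demand and level of service proportionally via
    row- and column-standardized impedance weights, so that total demand
    equals the population and total allocated service equals the total
    level of service. Includes binary, stepwise and Gaussian distance-decay
    functions, slack factors for modelling system inefficiency, inflation
    diagnostics comparing unadjusted and balanced runs, and accessibility
    disparity indices (equitable-share differences and spatial access
    ratios). Scenarios are read from and written to plain CSV (entity
    tables plus wide or long origin-destination cost matrices) and results
    can be exported as CSV or GeoJSON.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
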