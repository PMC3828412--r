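Package: iaqrisk
Title: Indoor Air Toxics Exposure Modelling and Inhalation Cancer Risk Assessment
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Probabilistic health-risk assessment for indoor air toxics such as
    formaldehyde and benzene in recently remodeled buildings. Fits lognormal
    concentration models to building-survey summary statistics by the method of
    moments, screens concentrations against Chinese and U.S. guideline values
    through hazard indices and analytic exceedance fractions, simulates
    time-weighted indoor personal exposure across home and office
    microenvironments by Monte Carlo, and converts exposure into lifetime
    excess cancer risk per million under alternative inhalation unit risk
    sets, with microenvironment disaggregation and post-remodeling
    concentration-decay scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus
Config/testthat/edition: 3
RoxygenNote: 7.3.3
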