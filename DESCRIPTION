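Package: popharvest
Title: Population-Based Modelling of Fruit Growth, Ripening and Harvest
    Strategy Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kinetic modelling of fruit growth (Gompertz) and colour change
    (hue decay with a mass-triggered biological switch) for individual fruit,
    joint calibration of season-level kinetic parameters and fruit-specific
    maximum mass and biological-age shift from on-plant time series, Monte
    Carlo simulation of virtual fruit populations, a no-intercept
    mixture-design price model mapping ripening-stage composition of a batch
    to its normalized wholesale price, and evaluation of single, fixed-interval
    and dynamic harvest strategies in terms of saleable mass, overripe waste
    and cumulative economic value. Includes reference parameter sets and a
    wholesale price survey for field tomato (cv. 'Savior') grown in the
    Vietnamese winter and summer seasons, and synthetic-data generators that
    emulate the corresponding field campaigns.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr
Config/testthat/edition: 3
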