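Package: timeoutMI
Title: Multiple Imputation of Timed-Out Page Views in Online Interventions
Version: 0.1.0
Authors@R: person("Q2", "Analytics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for measuring exposure time in web-delivered behavioural
    interventions when page views can end in an inactivity time-out.
    Navigation event logs are parsed into per-page viewing durations,
    time-outs are treated as missing data and multiply imputed with
    chained-equations (MICE) log-normal regression models, total time
    online is analysed with a zero-inflated Poisson model, and estimates
    are pooled across imputations with Rubin's rules.  A synthetic-cohort
    generator and a constant-assignment sensitivity analysis allow the
    whole pipeline to be exercised without access to trial data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
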