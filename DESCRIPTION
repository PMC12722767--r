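Package: icuresp
Title: Continuous Respiratory-State Monitoring and Ventilator Demand
    Forecasting for ICU Time Series
Version: 0.1.0
Authors@R:
    person("ICU Respiratory Monitoring", "Contributors", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Tools for building a continuous respiratory monitoring pipeline
    from irregular intensive-care time series: 5-minute gridding with
    clinically motivated forward-fill imputation policies, continuous
    PaO2/FIO2 (P/F ratio) estimation via a Severinghaus-Ellis physiological
    baseline and a nested regularized regression model, rule-based annotation
    of hypoxemic respiratory failure, mechanical ventilation and
    readiness-to-extubate states, label construction for four early-warning
    prediction tasks, gradient-boosted tree models with SHAP-based model
    inspection, event-based alarm evaluation with silencing policies and
    prevalence correction, and aggregation of per-patient risk scores into
    ICU-level ventilator-demand forecasts. Includes a synthetic ICU cohort
    simulator with known ground truth used as the primary test bed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
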