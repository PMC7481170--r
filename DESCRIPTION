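Package: climforce
Title: Warming-Level Climate Forcing for Controlled Ecosystem Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects a representative regional climate model (RCM) run from an
    ensemble and turns it into physically consistent, warming-level-stratified
    climate forcing for ecosystem manipulation experiments (ecotrons). Provides
    station and model series readers with explicit calendar and unit handling,
    per-variable skill metrics (bias, Perkins skill score, seasonal-cycle and
    percentile mean absolute errors, RMSE, Spearman rank correlation, Brier
    skill score) and ETCCDI-style climate indices (frost and summer days,
    Rx1day, CDD, CWD, growing season length, PRCPTOT), reproducible
    1-best-to-N-worst rankings with a precipitation-bias-decisive final
    selection, global-mean-temperature warming-window sampling, sub-daily
    forcing assembly with drizzle accumulation and humidity and pressure
    conversions, and a seeded stochastic weather generator so the whole
    pipeline is testable without external archives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    geosphere,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ncdf4,
    jsonlite,
    withr
Config/testthat/edition: 3
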