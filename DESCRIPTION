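Package: cer
Title: Causal Inference from Events of Relations in Binary Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Lag-resolved causal inference for binary (0/1) event time
    series based on events of relations: joint occurrences of a candidate
    effect event and a candidate cause event at a fixed delay. Coincidence
    counts at non-zero lags are compared against the zero-lag count with a
    Poisson approximation to the binomial test, which avoids any parametric
    model of the series themselves and therefore applies equally to
    stationary and non-stationary signals. Includes a neuronal-spike style
    interaction simulator (constant or random-walk event probabilities,
    arbitrary discrete delay distributions, multi-node acyclic networks),
    Monte-Carlo evaluation of detection and error rates, windowed-entropy
    and unit-root diagnostics for non-stationarity, plain-text series and
    config input/output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
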