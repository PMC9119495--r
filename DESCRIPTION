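Package: crowdstop
Title: Bayesian Sequential Stopping Rules for Crowdsourced Binary Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Decides when a crowdsourced binary image-classification task has
    accumulated enough volunteer ratings to be retired from circulation.
    A beta-binomial posterior for the probability of a positive rating is
    updated after every vote; a task is declared classified when a chosen
    posterior quantile clears a disagreement threshold, or deadlocked when
    the central credible interval sits strictly between the two thresholds.
    Includes precomputed decision-boundary tables (minimum majority ratings
    per dissent count, deadlock onset, cap-induced early retirement),
    a replay engine that applies the rule retrospectively to per-image
    rating streams and reports efficiency and reversal statistics, a
    synthetic-campaign generator, a Monte-Carlo sweep of error rates and
    time-to-conclusion across the latent rating probability, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
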