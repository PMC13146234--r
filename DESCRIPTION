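Package: shscount
Title: Secondhand-Smoke Exposure-Opportunity Counts from Passive Wi-Fi Sensing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pipeline for estimating day-level counts of smokers and
    passersby within a plausible secondhand-smoke radius around an outdoor
    smoking area, from anonymized Wi-Fi probe-request logs. Includes a
    ground-truth scenario simulator (Poisson arrivals, log-distance path
    loss, bursty probe emission), log ingest with salted-hash device
    anonymization, an eligibility funnel (business-hours filter, fixed-OUI
    exclusion, presence-episode construction, dwell-time screen),
    RSSI-band episode classification, device-to-person calibration against
    a manual observation window with threshold sensitivity analysis, and
    an exploratory random-forest stay classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lubridate,
    openssl,
    ranger,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
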