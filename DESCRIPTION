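Package: paintrial
Title: Time-Weighted Pain Endpoints and Gatekept Analysis for Acute-Pain Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Endpoint and statistical analysis machinery for randomized
    acute-pain trials that score analgesia with time-weighted composite
    endpoints. Computes summed pain intensity difference (SPID) and total
    pain relief (TOTPAR) over protocol assessment grids with the standard
    clinical imputation rules (night-sleep substitution, post-rescue
    carry-back windows, last observation carried forward), fixed-sequence
    gatekeeping for the primary comparisons, rescue-medication outcomes
    (exact Clopper-Pearson intervals, Kaplan-Meier time to first rescue,
    log-rank tests, zero-filled consumption summaries), and z-approximation
    sample-size and power calculations. A synthetic-trial simulator
    generates four-arm patient-controlled-analgesia datasets (lockout and
    hourly-cap dosing rules, rescue triggering, night-time missingness) so
    every stage of the pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
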