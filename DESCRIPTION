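Package: farrowcast
Title: Farrowing Onset Detection from Ear-Tag Accelerometry with CUSUM Control Charts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Early-warning detection of the onset of farrowing (parturition) in
    crate-confined sows from 1 Hz triaxial ear-tag accelerometer streams.
    Computes windowed distribution characteristics of the total-acceleration
    magnitude (including p-variation), transforms them into circadian-cancelling
    acceleration indices (Diff, Quot, Over, CumDi, CumQ, CumAv) based on
    day-offset moving-average baselines, and raises per-sow alarms with a
    one-sided CUSUM control chart parameterized on pre-farrowing reference days.
    Includes a synthetic cohort simulator (circadian activity rhythm, random
    sample dropout, pre-farrowing nest-building activity surge) and cohort-level
    evaluation of detection rates over the full factor grid of characteristics,
    indices, window lengths, moving-average ranges, allowance and control-limit
    parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table (>= 1.14.0),
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
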