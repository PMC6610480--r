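Package: ecrdes
Title: Discrete Event Simulation of an Endovascular Clot Retrieval Service
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discrete event simulation of a comprehensive stroke service
    delivering endovascular clot retrieval (ECR) for acute ischemic stroke.
    Four patient pathways (stroke, elective interventional neuroradiology,
    emergency interventional radiology, elective interventional radiology)
    compete for shared angiography suites, physicians and staff under
    non-preemptive priority queueing and shift-based capacity schedules.
    Includes a minimal event-calendar simulation kernel with atomic
    multi-resource seizure, named scenario transformations (exclusive use,
    second biplane suite, extended working hours, demand growth), wait-time
    and utilization metrics with standardized wait densities, a
    disability-free-life conversion, and closed-form queueing oracles
    (M/M/1, Erlang C) plus a brute-force single-server simulator for
    engine validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
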