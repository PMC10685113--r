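Package: thermocyte
Title: Software-in-the-Loop Simulation and Live-Cell Analytics for an
    Open-Source Stage-Top Temperature Controller
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the closed-loop thermal behaviour of an open-source,
    Arduino-class stage-top incubation system (discrete-time PID controller
    driving a lumped two-node waterblock/dish plant), characterises
    temperature logs (heating and cooling latency, stability statistics),
    and implements the companion live-cell imaging analytics: per-cell
    fluorescence trace extraction, delta-F/F baseline normalisation,
    threshold-based calcium transient detection with per-event width,
    height and area-under-curve kinetics, circularity morphometrics from
    label masks, viability summaries, and the comparison statistics used
    to contrast imaging temperatures. Seeded synthetic generators produce
    fluorescence traces, label masks and image stacks with known ground
    truth so the full pipeline is testable without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    yaml,
    tiff,
    png,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
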