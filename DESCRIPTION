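Package: mcaemboli
Title: Sizing and Cerebrovascular Impact of Air Emboli Detected by
    Transcranial Doppler During Cardiac Surgery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing intra-operative transcranial Doppler (TCD)
    microembolic signals. Converts measured embolus-to-blood ratios (MEBR)
    to air-bubble diameters by inverting a fluid-sphere acoustic backscatter
    model adjusted for haematocrit and Doppler geometry, estimates bubble
    volumes and diffusion-driven dissolve times, and predicts the resulting
    obstruction of middle-cerebral-artery end arterioles over time with a
    Monte-Carlo simulation of emboli routed through a Murray's-law
    bifurcating tree with Poiseuille flow and stiction-based lodging.
    Includes a synthetic-surgery generator that emulates stage-structured
    embolic event streams with ground truth for recovery testing, plus
    cohort-level descriptive and inferential statistics.
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
    tools,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
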