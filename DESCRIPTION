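Package: coldsense
Title: Fiber-Photometry, Indirect-Calorimetry and Fos-Colocalization
    Pipelines for Cold-Exposure Physiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Measurement-analysis pipelines for studies of the feeding and
    thermogenic response to mild cold exposure in mice. Implements lock-in
    demodulation of frequency-multiplexed fiber-photometry recordings,
    photobleaching (double-exponential) and isosbestic motion correction,
    session-median dF/F, temperature-ramp epoch quantification and
    food-response quality control; Weir-equation energy expenditure,
    respiratory quotient, hopper-derived energy intake, photoperiod
    reduction and cold-onset latency from indirect-calorimetry interval
    tables; threshold-and-particle-count Fos/reporter colocalization across
    serial sections; paired t, Holm-Sidak correction and a permutation
    treatment-by-time interaction test; plus synthetic-data generators with
    known ground truth so every stage is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    tiff,
    EBImage
Config/testthat/edition: 3
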