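Package: peergaze
Title: Gaze Analysis and Interpretation-Bias Modelling for Peer-Scene Free Viewing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for free-viewing eye-tracking studies of
    social-scene interpretation: cleaning of 300 Hz binocular gaze and pupil
    recordings (Savitzky-Golay gaze smoothing, median pupil filtering, blink
    rejection, sample repair, baseline and drift correction), trial- and
    participant-level quality control, velocity-dispersion-duration fixation
    detection, area-of-interest dwell-time extraction, questionnaire scoring
    (SAS-A, PDS), and information-theoretic inference: all-subsets linear
    mixed models with crossed subject and scene random intercepts, Akaike
    weights, and full model-averaged coefficients with unconditional standard
    errors. Includes a synthetic-data generator with known ground-truth gaze
    events and a known generative rating model, so that every stage of the
    pipeline can be validated by parameter and event recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lme4,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    withr,
    zoo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
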