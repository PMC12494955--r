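Package: brainref
Title: Normative Brain-Volume Reference Curves, Field-Strength Robustness,
    and Atrophy Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Fits shape-constrained penalized B-spline expectile curves
    (5th, 50th and 95th expectiles) of ICV-normalized regional brain
    volumes against age, quantifies the robustness of such reference
    curves across MRI field strengths (1.5T vs 3T) with symmetric
    percentage error metrics and a label-shuffling permutation null, and
    assesses atrophy both per structure and with the composite
    hippocampal-amygdalo-ventricular (HAVAs) score.  Includes a synthetic
    cohort generator emulating lifespan volume trajectories, field-strength
    measurement bias, Alzheimer-type atrophy and traveling-subject designs,
    plus an end-to-end reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    splines,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
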