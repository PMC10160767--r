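Package: nirskill
Title: fNIRS Analysis of Motor-Skill Learning with Short-Separation GLM and
    LC-CUSUM Learning Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for longitudinal functional near-infrared spectroscopy
    (fNIRS) studies of motor-skill acquisition, built around block-design
    training of the Fundamentals of Laparoscopic Surgery (FLS) suturing task.
    Provides containers and plain-text serialization for probe montages,
    multichannel recordings and stimulus designs; a synthetic-study generator
    with known ground truth (task-locked hemodynamics, superficial scalp
    contamination, physiological oscillations, drift, motion artifacts, and
    behavioral learning curves); a preprocessing chain (optical density,
    hybrid spline/Savitzky-Golay motion correction, zero-phase Butterworth
    bandpass in the neurovascular coupling band, modified Beer-Lambert law);
    hemodynamic response function estimation by ordinary least squares on a
    Gaussian basis with short-separation nuisance regression; channel-level
    activation statistics across training days and learner subgroups;
    FLS-style performance scoring; and LC-CUSUM learning-curve assessment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
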