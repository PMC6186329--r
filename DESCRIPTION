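Package: gaitanfis
Title: Neuro-Fuzzy Classification of Neurodegenerative Gait Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies gait in neurodegenerative disease (amyotrophic
    lateral sclerosis, Parkinson's and Huntington's disease) against
    healthy controls from stride-interval dynamics. Implements a
    first-order Sugeno adaptive neuro-fuzzy inference system with
    generalized bell membership functions over a full grid-partition rule
    base, trained by particle swarm optimization with a linearly decaying
    inertia weight against a root-mean-square-error fitness, and a
    minimum-distance subject classifier evaluated by leave-one-subject-out
    cross-validation. Includes readers and writers for PhysioNet-style
    gait record files, the signal-conditioning chain (start-up removal,
    median-referenced outlier rejection, walking-turn segmentation), a
    calibrated synthetic cohort generator, and severity stratification of
    the patient groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
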