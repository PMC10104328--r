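Package: equifatigue
Title: Detecting Equine Fatigue from Body-Mounted Inertial Sensor Gait Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for detecting exercise-induced fatigue in sport
    horses from body-mounted inertial measurement units (IMUs). Raw tri-axial
    acceleration and angular-velocity streams from seven sensor locations
    (sacrum, withers, poll, four limbs) are low-pass filtered, segmented into
    strides at right-front hoof-on events, and reduced to 52 per-stride
    biomechanical features (gait-event durations, speed, movement-symmetry
    indices, angular ranges of motion, and cyclically integrated displacement
    ranges). Features are normalized within horse, aggregated to 104
    mean-and-variability values per horse and trial, ranked by neighborhood
    component analysis, and fed through greedy forward selection into
    leave-one-subject-out classifiers (SVM, k-nearest neighbour, decision
    tree, naive Bayes, logistic regression). A seeded synthetic gait-signal
    generator with full ground truth makes every stage testable without
    animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    rpart,
    class,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
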