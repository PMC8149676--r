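Package: sleepreplay
Title: Slow Oscillation-Spindle Coupling and Memory Reactivation Analysis for Sleep EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection of slow oscillations, sleep spindles and their temporal
    coupling in NREM scalp EEG; quantification of slow oscillation-spindle
    phase coupling with circular statistics (Rayleigh test, circular-linear
    and partial circular-linear correlation); wake-to-sleep temporal
    generalization decoding of stimulus category with shuffled-label
    surrogate baselines and cluster-based permutation inference; and
    signal-detection-theory memory scoring (d-prime, cued-recall retention).
    Includes a synthetic sleep-EEG generator with known ground truth (planted
    slow oscillations, von Mises phase-coupled spindle bursts, injected
    category-specific reactivation patterns, and linked recognition/recall
    behavior) so every stage of the pipeline can be validated end to end,
    plus minimal EDF and BrainVision readers and writers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    MASS,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
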