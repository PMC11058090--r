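Package: synergait
Title: Muscle Synergy Analysis of Perturbed Walking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for extracting and characterizing muscle synergies from
    multi-channel surface electromyography (EMG) recorded during perturbed
    treadmill walking. Provides EMG envelope conditioning (zero-phase
    Butterworth filtering, rectification, amplitude normalization), gait-event
    detection from foot-mounted accelerometry, time normalization of gait
    cycles to a fixed 200-point grid, Gaussian non-negative matrix
    factorization with repetition averaging and rank selection, k-means-based
    classification of activation patterns into the four fundamental walking
    synergies, and spatiotemporal synergy metrics (cosine similarity to a
    reference cycle, full width at half maximum, circular center of activity).
    A seeded synthetic-data generator produces gait-cycle EMG with known
    ground truth (planted synergies, perturbation-induced timing shifts and
    pattern widening) for validation of every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
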