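Package: nirselect
Title: Wrapper-Based Metaheuristic Feature Selection for fNIRS Brain-Computer Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for selecting task-discriminative features from functional
    near-infrared spectroscopy (fNIRS) oxyhemoglobin recordings. Provides a
    synthetic session generator with known ground-truth informative channels,
    Butterworth band-limiting and epoching of continuous recordings, extraction
    of five temporal statistics per channel (mean, peak, slope, skewness,
    kurtosis), a k-nearest-neighbor wrapper cost balancing holdout accuracy
    against subset size, seven continuous population metaheuristics (particle
    swarm, cuckoo search, firefly, bat, flower pollination, whale, and grey
    wolf optimization) under a single seeded run contract, an exhaustive-subset
    oracle for small problems, and repeat-run evaluation with Welch t-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    FNN
Config/testthat/edition: 3
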