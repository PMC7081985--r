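Package: vocolock
Title: Vocalization-Locked Analysis of Fronto-Striatal Field Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline linking low-frequency field-potential
    oscillations in the bat frontal auditory field (FAF) and caudate
    nucleus (CN) to vocal output. Classifies echolocation pulses and
    communication calls from audio, extracts vocalization-locked LFP
    epochs, builds randomization trials, maps time-frequency effect
    sizes (Cliff's Delta) between call conditions with multitaper
    spectrograms, decodes call type from band power with an RBF-kernel
    SVM including label-shuffle controls, computes inter-areal
    coherence with percentile significance masks, and quantifies
    spike-LFP phase locking with bootstrap vector-strength statistics.
    Includes a seedable synthetic-session generator emulating the
    recording structure (1/f LFP background, injected band bursts,
    inter-areal coherent components, phase-locked spiking) with a
    ground-truth record for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    jsonlite,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
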