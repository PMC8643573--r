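Package: mrcposc
Title: Movement-Related Cortical Potentials and Sensorimotor Oscillations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of movement-related cortical potentials (MRCP) and
    event-related (de)synchronization (ERD/ERS) around cued ankle
    dorsiflexion from joint EEG (250 Hz, 17-channel 10-20 montage) and
    surface EMG (1000 Hz, bilateral tibialis anterior and soleus)
    recordings. Provides EDF/EDF+ session I/O, Teager-Kaiser energy
    EMG onset detection, zero-phase Butterworth preprocessing paths for
    the slow-potential (0.05-5 Hz) and oscillatory (0.05-50 Hz) signals,
    extended-infomax ICA with automated artifact-component rejection,
    onset-locked epoching with quality control, single-trial MRCP
    features (peak negativity, NS1, NS2, rebound rate, MRCP-EMG
    latency), surface small-Laplacian filtering, five-cycle Morlet
    time-frequency maps with baseline-normalized ERD/ERS, bootstrap and
    permutation significance maps, one-way ANOVA with Tukey post hoc
    on feature tables, and a ground-truth synthetic cohort generator
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, graphics, grDevices, signal, yaml
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
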