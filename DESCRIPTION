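Package: choicekernels
Title: Psychophysical and Neural Choice Kernels for Evidence-Accumulation Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for contrast-discrimination
    decision experiments with region-of-interest spectral (MEG-like) power.
    Provides a synthetic task generator (drifting-grating stimulus, QUEST
    adaptive staircase, noisy weighted-accumulator observer, structured
    spectro-temporal power tensors), psychophysical reverse-correlation
    kernels (ROC-AUC per sample position), multitaper time-frequency
    estimation with baseline normalization and hemispheric lateralization,
    multivariate choice and contrast decoding (linear SVM and ridge
    regression with cross-validation), neural-activity kernels with
    stimulus residualization, lagged coupling between motor choice signals
    and visual low-frequency kernels, and group-level inference
    (hierarchical Bayesian Student-t AUC model, threshold-free cluster
    enhancement permutation tests, FDR correction).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    glmnet,
    rjags,
    coda,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
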