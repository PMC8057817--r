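Package: offdyn
Title: Network Dynamics of Transient Population OFF Responses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation, closed-form theory and data analysis of transient
    OFF responses in neural populations modeled as low-rank linear recurrent
    networks. Provides matrix-exponential propagation of linear rate
    dynamics, amplification criteria based on the symmetric part of the
    connectivity, rotational-channel construction and closed-form
    trajectories, preprocessing of trial-structured calcium-imaging-like
    activity, ridge and reduced-rank ridge estimation of effective
    connectivity with cross-validated hyperparameter selection, a
    basis-function single-cell model, subspace-geometry analyses
    (cross-validated PCA, principal-angle overlaps, shuffle controls),
    per-stimulus transient-channel decomposition, single-trial variability
    amplification statistics, pairwise stimulus decoding, tensor
    maximum-entropy surrogate controls, and a synthetic-data generator
    emulating the statistical structure of pooled auditory-cortex
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
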