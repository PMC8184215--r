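Package: cpstim
Title: Stimulus-Dependent Choice Probability Analysis for Sensory Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize how activity-choice covariations of sensory
    neurons depend on the stimulus in two-choice perceptual decision tasks.
    Implements the exact choice-probability (CP) solution of the bivariate
    Gaussian decision-threshold model via Owen's T function, its linear
    approximation through the threshold-induced modulation factor h(pCR), a
    feedforward population model with shared multiplicative gain fluctuations
    predicting cell-specific CP(pCR) profiles, weighted estimation of
    within-cell CP(pCR) profiles from trial tables, surrogate-based
    significance tests with choice-conditioned z-scoring, cosine-distance
    k-means clustering of profile shapes, and Poisson generalized linear
    models with stimulus-choice interaction terms compared by cross-validated
    relative increase in likelihood. A synthetic-data simulator generates
    trial tables from the full generative model (tuning curves, shared gain,
    Poisson spiking, linear readout, threshold choice).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
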