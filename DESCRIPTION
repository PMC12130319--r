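Package: plastnn
Title: Biologically Inspired Synaptic-Diversity Mechanisms for Neural Network Training
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Drop-in training mechanisms modeled on synaptic diversity in
    biological neural networks: fuzzy learning rates (fixed per-weight random
    gradient multipliers modeling diverse synaptic plasticity), weight
    rejuvenation (probabilistic reinitialization of small weights modeling
    spontaneous dendritic spine remodeling), and weight splitting
    (multi-synaptic connectivity with preserved parameter count). Includes a
    minimal explicit-backprop network and SGD trainer integrating the
    mechanisms, seedable generators for classification fixtures and chaotic
    time series (Thomas attractor, two-level Lorenz'96), an
    optimization-based gradient-inversion attack with a normalized
    reconstruction-error metric, and matrix-free Hessian extreme-eigenvalue
    estimation with eigenvalue MinMax-ratio maps over 2-D loss surfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
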