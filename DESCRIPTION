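Package: molgraphnn
Title: Dual-Branch Spectral/Isomorphic Graph Networks for Molecules with
    Gradient-Based Edge Attacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Molecular property prediction on SMILES-derived graphs with a
    56-dimensional atom and 9-dimensional bond featurization, a Chebyshev
    spectral graph-convolution autoencoder pre-trained with a contrastive
    latent-perturbation objective, and a dual-branch classifier combining the
    pre-trained spectral backbone with a graph-isomorphic (Weisfeiler-Lehman
    style) branch through per-layer additive links. Also implements a
    white-box adversarial attack that drops low-sensitivity edges using
    gradients of the contrastive loss with respect to reconstructed adjacency
    matrices, scheduled by random draws from a sine wave. All training,
    back-propagation and optimisation are implemented in base R matrix
    algebra; SMILES are parsed through a bundled RDKit helper script.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
SystemRequirements: Python (>= 3.8) with the RDKit package, available as
    'python' on the PATH.
Config/testthat/edition: 3
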