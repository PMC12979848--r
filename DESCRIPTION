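Package: qpin
Title: Quantum-Inspired Dynamics and Link Prediction on Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models protein interaction networks as open quantum systems.
    Builds graph-structured many-body operators (swap-based quantum graph
    Laplacians, quantum graph gradients and divergences), evolves network
    density matrices under Lindblad master-equation dynamics with
    dephasing, binding and thermal decoherence channels, and scores
    candidate protein pairs for interaction through time-integrated
    measurement operators with an exponential binding-memory kernel.
    Includes quantum-information network measures (von Neumann entropy,
    interaction entropy, l1 coherence, modular entanglement bounds), a
    variational quantum eigensolver with parameter-shift gradients and
    Adam updates, a planted-partition synthetic network generator with
    correlated node features, and an end-to-end prediction pipeline with
    internal ROC/threshold metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
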