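Package: symptomnet
Title: Cross-Sectional and Cross-Lagged Network Analysis of Binary Symptom Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates cross-sectional Ising networks of binary symptoms by
    node-wise L1-penalized logistic regression with extended-BIC model
    selection and AND-rule edge assembly, and directed cross-lagged panel
    networks by per-outcome LASSO logistic regression with ten-fold
    cross-validation and the one-standard-error rule.  Includes strength,
    closeness and betweenness centrality for weighted networks, permutation
    invariance tests of network differences (maximum edge difference and
    global strength), bootstrap accuracy and case-dropping stability
    diagnostics (correlation-stability coefficients), descriptive paired
    statistics for two-wave panels, scoring and risk classification for the
    Problem Gambling Severity Index, and a synthetic two-wave binary panel
    generator with known ground-truth network structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
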