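Package: clinnet
Title: Simulation and Analysis of Clinician Peer-Network Experiments on
    Treatment Bias
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for simulating and analysing three-round egalitarian
    peer-network experiments in which practicing clinicians assess a
    standardized cardiac chest-pain case and recommend one of four
    treatment options. Provides the clinical scoring rules (HEART score
    and its intermediate-risk anchor), generation of degree-regular
    rewired communication networks, an agent-based generator of clinician
    estimates and recommendations under network and control conditions,
    bias and accuracy metrics (min-max normalized diagnostic accuracy,
    undertreatment/guideline gaps and inequity in percentage points,
    odds of unsafe undertreatment, the revision coefficient), and a
    trial-level statistical framework (bootstrapped control groups,
    exact Wilcoxon rank-sum and signed-rank tests, cluster-robust
    logistic regression), together with a CSV/JSON interface and a small
    command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
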