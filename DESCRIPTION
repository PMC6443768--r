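Package: netrecip
Title: Network Reciprocity via Direct Reciprocity and Model-Predictive
    Strategy Update
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Agent-based model of the networked prisoner's dilemma in
    which cooperators practice direct reciprocity by temporarily
    abstaining from play with neighbors known to defect, while all agents
    revise their strategy by best response over a finite predictive
    horizon.  Provides the network generators used in studies of network
    reciprocity (ring and planar lattices, single-scale, scale-free,
    Holme-Kim, star, complete), the statistics of abstention periods, the
    forecast recursions and expected-gain formulas of the predictive
    update rule, closed-form persistence and fixation thresholds, and
    compiled Monte Carlo experiment runners that estimate invasion and
    fixation thresholds from return sweeps, single-seed invasion
    probabilities, and a pairwise-comparison imitation baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
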