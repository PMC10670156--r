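Package: edenr
Title: Qualitative Discrete-Event Networks for Ecosystem Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Rule-based qualitative modeling of ecosystem dynamics with
    Boolean and multivalued variables. Models are sets of if-then rules
    (condition on threshold levels, atomic realization) executed under
    asynchronous or synchronous update semantics; all possible trajectories
    are explored exhaustively (possibilistic, non-probabilistic
    non-determinism) into a state-transition graph. The graph is analyzed
    topologically: stable states (deadlocks), cyclic and complex strongly
    connected components, basins of transient states, and a hierarchical
    transition graph condensing them. A fixed set of model-checking query
    patterns (reachability, invariance, avoidability, stability, event
    necessity and sufficiency) answers ecological questions such as whether
    a collapse is avoidable or whether an extinction event is a necessary
    condition for a community to persist.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
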