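Package: frontierBO
Title: Batch Bayesian Optimization of Laboratory Protocols via
    Partition Trees and Convex-Hull Frontiers
Version: 0.1.0
Authors@R:
    person("frontierBO", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Deterministic, batch/asynchronous Bayesian optimization for
    closed-loop tuning of laboratory experimental protocols.  The search
    space is scaled to the unit hypercube and explored with a hierarchical
    trisection tree (DIRECT-style); a Gaussian-process surrogate with a
    Matern 5/2 kernel supplies upper confidence bounds, and batches of up
    to k experiments are selected from the upper convex hull ("frontier")
    of unevaluated leaves encoded as (tree depth, UCB).  Includes endpoint
    objectives for mass-spectrometry grid sweeps (peak height, width, SNR
    and their combinations) and chromatographic resolution, conventional
    batch-BO baselines (Thompson sampling, EI, PI, UCB, random, Latin
    hypercube sampling), a discrete-event simulated cloud laboratory, and
    seeded synthetic fixture generators so the whole system is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
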