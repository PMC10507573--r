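Package: playsdp
Title: Stochastic Dynamic Programming Models of Juvenile Play as Practice
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Finite-horizon stochastic dynamic programming models of a juvenile
    mammal allocating free time among foraging, play and rest, where play acts
    as low-risk practice that improves an instrumental ability. Provides exact
    backward induction over the (energy, ability, time) state grid for four
    model variants (ability reducing foraging predation risk, raising foraging
    success, or raising terminal reproductive success), deterministic forward
    propagation of a cohort under the optimal policy, an individual-based
    Monte-Carlo simulator for verification, and one-at-a-time parameter
    sensitivity sweeps reporting where lifetime play exceeds a threshold.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
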