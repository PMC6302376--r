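Package: mocudesign
Title: Objective-Based Experimental Design for Markovian Gene Regulatory
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for intervention and experimental design in Markovian gene
    regulatory networks modelled as Boolean networks with perturbation. Builds
    transition probability matrices from per-gene conditional probability
    matrices, tracks uncertain conditional probabilities with beta-Bernoulli
    conjugate priors, derives intrinsically Bayesian robust (IBR) stationary
    control policies by value iteration on an effective transition probability
    matrix, approximates them with mean-first-passage-time (MFPT) policies, and
    ranks candidate experiments by the mean objective cost of uncertainty
    (MOCU) so that the experiment that most reduces intervention cost is
    performed first. Includes random network generation, two curated
    real-network fixtures (a TP53 damage-response pathway and a mutated
    mammalian cell cycle), sequential design, and a benchmark harness.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
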