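Package: micropop
Title: Stochastic Growth of Metabolically Heterogeneous Micro-Populations
    in Finite Environments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models an ensemble of micro-populations (for example, bacteria
    inoculated into microdroplets) grown to saturation of a finite resource,
    where single cells differ in division rate and in yield (divisions
    supported per unit resource). Provides exact continuous-time (Gillespie)
    and embedded jump-chain simulators of the division process, exact
    final-state distributions on the resource-exhaustion stopping line by
    path enumeration and by dynamic programming over the phenotype lattice,
    deterministic stopping-time solutions including a closed form for
    division-rate ratio two and its small-inoculum expansion, and Polya-urn
    analytics: the Beta-Binomial composition law, its coefficient of
    variation and inoculum scaling, a Gamma-representation sampler of the
    limiting scaled composition, and the yield-mapping that transfers
    uniform-yield results to variable-yield populations to give the
    distribution and moments of final population size.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
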