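Package: mscrecomb
Title: Multispecies Coalescent Simulation and Inference under Intralocus
    Recombination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates multilocus sequence alignments under the multispecies
    coalescent (MSC) and MSC-with-introgression (MSci) models with intralocus
    recombination (a constrained Hudson ancestral recombination graph inside a
    species tree or network, followed by JC69 sequence evolution along segment
    genealogies), and re-infers species trees and population parameters by
    Bayesian MCMC under the standard no-recombination MSC assumption.
    Provides the evaluation statistics of frequentist simulation studies
    (species-tree recovery probabilities, clade posteriors, credible-interval
    coverage, bias and relative root-mean-square error, per-locus
    recombination-event summaries, and segment-genealogy comparisons) and a
    factorial experiment harness with reproduction presets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    ape,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
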