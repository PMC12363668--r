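Package: evodiv
Title: Diversity Timescales of Neutral Evolution on Population-Structure Graphs
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how population structure maintains neutral
    diversity under evolutionary graph dynamics. Implements birth-death (bd)
    and death-birth (db) updating on strongly connected graphs, exact expected
    absorption (consensus / total coalescence) times via the full labeled
    Markov chain and a set-partition lumped chain, closed-form times for
    complete graphs, cycles and stars, two-type fixation probabilities,
    a compiled Monte-Carlo simulator with characteristic (diversity-vs-time)
    curves, isomorph-free enumeration of small connected graphs, and
    comparative analyses (Pareto fronts of bd vs db times, degree entropy,
    log-log scaling slopes).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    igraph,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
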