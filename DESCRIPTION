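Package: rangewalk
Title: Annihilating-Coalescing Domain-Wall Random Walks for Microbial Range Expansions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the genetic demixing of many competing microbial strains at
    the frontier of a range expansion as a one-dimensional ring of annihilating and
    coalescing domain-wall random walkers with deterministic selection biases, in
    both linear and radially inflating geometries. Computes ensemble observables
    (average strain fractions, two-point angular correlation functions,
    heterozygosity, annihilation asymmetry, single-sector statistics), closed-form
    neutral theory and key-parameter arithmetic (selection length scale, inflationary
    selection parameter, characteristic angular correlation length, inflationary
    crossover), and inference procedures that recover the wall diffusion constant,
    selection length scales and wall velocities from observed curves via nonlinear
    least squares and collapse onto simulated universal correlation functions.
License: MIT
Encoding: UTF-8
Imports: Rcpp, stats, utils, tools, jsonlite, optparse
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
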