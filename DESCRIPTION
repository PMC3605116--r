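Package: phagecoevo
Title: Bacteria-Phage Coevolution in a Resource-Limited Chemostat
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates antagonistic coevolution between bacteria and
    bacteriophage in a well-mixed chemostat. A multi-strain Monod-growth
    model couples resource dynamics, host growth, and phage predation
    under a lock-and-key infection kernel (Gaussian or strict genetic
    matching), with stochastic mutation injecting new strains on a binned
    one-dimensional genotype line. Includes genotype-to-growth-rate
    landscape generators (single-peak, dynamic two-peak, multi-peak,
    rugged-slope), closed-form steady-state theory (resource-limited and
    phage-limited equilibria, sequential-introduction diversity
    prediction), community observables (fitness fields, growth-lysis
    correlation, genotype range, strain richness), and experiment drivers
    for diversification, evolvability, and sensitivity ensembles. The
    integration core is written in C++ for long eco-evolutionary runs.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
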