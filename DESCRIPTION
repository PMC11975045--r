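Package: srb
Title: Structured Random Binding Model of Protein-Protein Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulator and analytics for structured random binding (SRB), a
    minimal statistical-physics model of protein-protein interactions.
    Proteins are collections of peptide epitopes whose sliding sequence
    windows map to structural motifs carrying quenched random pairwise
    couplings.  The package provides the exact extreme-value (Gumbel)
    statistics of nonspecific binding between random proteins, the
    condensation (freezing) transition of the complex Boltzmann measure
    diagnosed by the participation ratio, mutation-selection dynamics of
    binding affinity under a Fermi survival rule with a coevolving
    threshold, and the statistical bias of homodimers toward antiparallel
    isologous interfaces.  A compiled kernel makes population-scale
    affinity evolution tractable; scripted experiments reproduce the
    model's headline simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    Biostrings
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
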