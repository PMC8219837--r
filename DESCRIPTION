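Package: trnadesign
Title: De Novo Design and Rational Editing of Nonsense Suppressor tRNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for computational repurposing of transfer RNAs into
    nonsense suppressors. Implements a canonical tRNA coordinate system
    with arm segmentation, a nearest-neighbor secondary-structure energy
    model with minimum-free-energy folding and a McCaskill-style
    equilibrium partition function, and a constrained sequence-design
    pipeline that generates candidate tRNAs under fixed-nucleotide
    restraints (aminoacylation identity elements, anticodon, conserved
    tertiary interactions) and ranks them by the equilibrium probability
    of folding into the canonical cloverleaf. Also provides a rational
    tRNA-editing grammar (anticodon swaps, TPsiC-stem and D-arm
    transplants, variable-loop extension, acceptor-stem pair
    substitutions), an additive elongation-factor binding-affinity score,
    and validation reports, with FASTA, Vienna dot-bracket and TSV I/O
    and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
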