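# Verbatim design-scheme fixtures: the secondary-structure target and the
# fixed-nucleotide restraint rows (tertiary interactions, AlaRS
# aminoacylation identity elements, anticodon, and their union) rendered as
# 76-character templates with '.' at unrestrained positions. These literal
# strings are kept independent of the programmatic restraint assembly in
# build_restraints(), so agreement between the two is a real consistency
# check, not a tautology.

TABLE1_SECONDARY <-
  "(((((((..((((........)))).(((((.......))))).....(((((.......))))))))))))...."
TABLE1_TERTIARY_FULL <-
  ".......UAGCUCAG..GG.AGAGC..................G.G.C.....UUCGAUU................"
TABLE1_ALARS_IDENTITY <-
  "GGGG...............G................................................CUCCACCA"
TABLE1_NEW_ANTICODON <-
  ".................................CUA........................................"
TABLE1_COMBINED <-
  "GGGG...UAGCUCAG..GGGAGAGC........CUA.......G.G.C.....UUCGAUU........CUCCACCA"

#' Design-scheme template rows
#'
#' The four 76-character design templates: the cloverleaf secondary-structure
#' target in dot-bracket notation, the tertiary-interaction base template
#' (full mode), the AlaRS identity-element template, the new-anticodon (CUA)
#' template, and their union ("combined"). Dots mark unrestrained positions.
#'
#' @return named character vector with elements `secondary_structure`,
#'   `tertiary`, `alars_identity`, `new_anticodon`, `combined`.
#' @export
table1_rows <- function() {
  c(secondary_structure = TABLE1_SECONDARY,
    tertiary = TABLE1_TERTIARY_FULL,
    alars_identity = TABLE1_ALARS_IDENTITY,
    new_anticodon = TABLE1_NEW_ANTICODON,
    combined = TABLE1_COMBINED)
}

# AlaRS identity elements: acceptor-stem centered (G1-G4, the discriminator
# and 3' strand C69-U70-C71-C72 including the G3.U70 wobble partner, A73
# discriminator, C74-C75-A76 CCA) plus the conserved mid-sequence G20;
# independent of the anticodon.
alars_identity_map <- function() {
  c(`1` = "G", `2` = "G", `3` = "G", `4` = "G", `20` = "G",
    `69` = "C", `70` = "U", `71` = "C", `72` = "C",
    `73` = "A", `74` = "C", `75` = "C", `76` = "A")
}
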