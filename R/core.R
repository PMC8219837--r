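# Canonical tRNA coordinate system and sequence container.
#
# Canonical position labels follow the standard 1..76 tRNA convention
# (anticodon at 34-36, CCA tail at 74-76); extra variable-loop residues are
# labeled 47a, 47b, ... in insertion order and sort between 47 and 48.
# Labels are 1-based to match the field's notation (G3-U70, pairs 49-65);
# sequence indices are ordinary 1-based R indices, and the conversion lives
# entirely in the canonical_numbering object.

RNA_BASES <- c("A", "C", "G", "U")

#' Normalize an RNA sequence string
#'
#' Uppercases, converts T to U (DNA input and U-like placeholders are read as
#' uridine; modified bases are out of scope) and validates the alphabet.
#'
#' @param seq character scalar.
#' @return normalized character scalar over A/C/G/U.
#' @export
normalize_rna <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- chartr("t", "u", toupper(seq))
  s <- chartr("T", "U", s)
  bad <- setdiff(unique(strsplit(s, "")[[1]]), RNA_BASES)
  if (length(bad))
    stop("non-ACGU(T) characters in sequence: ", paste(bad, collapse = ", "))
  s
}

#' Canonical numbering for a tRNA sequence
#'
#' Maps each sequence index to a canonical position label. Labels 1..47 map to
#' indices 1..47, insertion labels 47a, 47b, ... to the next `insertions`
#' indices, and labels 48..76 to the remainder.
#'
#' @param seq_length sequence length; must equal `76 + insertions`.
#' @param insertions number of variable-loop insertions (>= 0).
#' @return a `canonical_numbering` object: `labels` (label per sequence
#'   index, in order) and `index_of` (named integer, label -> index).
#' @examples
#' nb <- canonical_map(76)
#' nb$index_of[["34"]]  # anticodon first position
#' @export
canonical_map <- function(seq_length, insertions = 0L) {
  stopifnot(length(seq_length) == 1L, length(insertions) == 1L,
            insertions >= 0)
  if (seq_length != 76L + insertions)
    stop("length mismatch: seq_length (", seq_length,
         ") must equal 76 + insertions (", 76L + insertions, ")")
  ins <- if (insertions > 0) paste0("47", letters[seq_len(insertions)])
         else character(0)
  labels <- c(as.character(1:47), ins, as.character(48:76))
  index_of <- seq_along(labels)
  names(index_of) <- labels
  structure(list(labels = labels, index_of = index_of,
                 insertions = as.integer(insertions)),
            class = "canonical_numbering")
}

#' @export
print.canonical_numbering <- function(x, ...) {
  cat("canonical_numbering:", length(x$labels), "positions,",
      x$insertions, "variable-loop insertion(s)\n")
  invisible(x)
}

label_index <- function(numbering, labels) {
  labels <- as.character(labels)
  idx <- numbering$index_of[labels]
  if (anyNA(idx))
    stop("unknown canonical label(s): ",
         paste(labels[is.na(idx)], collapse = ", "))
  unname(idx)
}

#' Construct a tRNA object
#'
#' @param seq RNA string (T accepted and normalized to U).
#' @param id record label.
#' @param numbering optional `canonical_numbering`; by default inferred as
#'   76 nt + variable-loop insertions for sequences of length >= 76.
#' @param notes free-text provenance.
#' @return a `trna` object.
#' @examples
#' t <- trna(paste0(strrep("A", 73), "CCA"), id = "toy")
#' check_cca(t)
#' @export
trna <- function(seq, id = "trna", numbering = NULL, notes = "") {
  seq <- normalize_rna(seq)
  n <- nchar(seq)
  if (is.null(numbering)) {
    if (n < 76L)
      stop("sequence '", id, "' is ", n,
           " nt; lengths below 76 need an explicit numbering")
    numbering <- canonical_map(n, n - 76L)
  }
  if (length(numbering$labels) != n)
    stop("numbering covers ", length(numbering$labels),
         " positions but sequence has ", n)
  structure(list(id = id, seq = seq, numbering = numbering, notes = notes),
            class = "trna")
}

`%+%` <- function(a, b) paste0(a, b)

#' @export
print.trna <- function(x, ...) {
  cat(">", x$id, " (", nchar(x$seq), " nt",
      if (check_cca_quiet(x)) ", CCA end" else "", ")\n", sep = "")
  cat(x$seq, "\n")
  invisible(x)
}

trna_chars <- function(trna) strsplit(trna$seq, "")[[1]]

#' Base(s) at canonical label(s)
#' @param trna a `trna`.
#' @param labels canonical labels (numbers or strings like "47a").
#' @return character vector of bases.
#' @export
base_at <- function(trna, labels) {
  trna_chars(trna)[label_index(trna$numbering, labels)]
}

replace_at <- function(trna, labels, bases) {
  ch <- trna_chars(trna)
  ch[label_index(trna$numbering, labels)] <- bases
  trna$seq <- paste(ch, collapse = "")
  trna
}

# Arm regions partition the canonical labels exactly; the two acceptor-stem
# strands flank everything else, connector residues 8-9 are counted with the
# D-arm and 26 with the anticodon arm.
arm_region_labels <- function(numbering) {
  ins <- grep("^47[a-z]$", numbering$labels, value = TRUE)
  list(acceptor_5p  = as.character(1:7),
       d_arm        = as.character(8:25),
       anticodon_arm = as.character(26:43),
       variable     = c(as.character(44:47), ins, "48"),
       t_arm        = as.character(49:65),
       acceptor_3p  = as.character(66:72),
       tail         = as.character(73:76))
}

#' Cloverleaf arm segmentation
#'
#' Stems as paired canonical labels and loops as label runs: acceptor stem
#' 1-72 ... 7-66, D-stem 10-25 ... 13-22 with loop 14-21, anticodon stem
#' 27-43 ... 31-39 with loop 32-38, variable loop 44-48, T-stem 49-65 ...
#' 53-61 with loop 54-60, and the 3' tail 73-76.
#'
#' @return list with `stems` (named list of 2-column label matrices) and
#'   `loops` (named list of label vectors).
#' @export
arm_segments <- function() {
  stem <- function(i, j) cbind(as.character(i), as.character(j))
  list(
    stems = list(
      acceptor  = stem(1:7, 72:66),
      d_stem    = stem(10:13, 25:22),
      anticodon = stem(27:31, 43:39),
      t_stem    = stem(49:53, 65:61)),
    loops = list(
      d_loop         = as.character(14:21),
      anticodon_loop = as.character(32:38),
      variable       = as.character(44:48),
      t_loop         = as.character(54:60),
      tail           = as.character(73:76)))
}

#' Extract a tRNA region
#'
#' @param trna a `trna` with complete canonical numbering.
#' @param region one of `acceptor`, `d_arm`, `anticodon_arm`, `variable`,
#'   `t_arm`, `tail`, `anticodon`. `acceptor` returns both strands (labels
#'   1-7 then 66-72); `anticodon` returns exactly labels 34-36.
#' @return list with `seq` (5'->3' residues) and `labels`.
#' @export
segment <- function(trna, region) {
  regions <- arm_region_labels(trna$numbering)
  labels <- switch(region,
    acceptor      = c(regions$acceptor_5p, regions$acceptor_3p),
    d_arm         = regions$d_arm,
    anticodon_arm = regions$anticodon_arm,
    variable      = regions$variable,
    t_arm         = regions$t_arm,
    tail          = regions$tail,
    anticodon     = as.character(34:36),
    stop("unknown region '", region, "'; expected one of acceptor, d_arm, ",
         "anticodon_arm, variable, t_arm, tail, anticodon"))
  list(seq = paste(base_at(trna, labels), collapse = ""), labels = labels)
}

check_cca_quiet <- function(trna) {
  n <- nchar(trna$seq)
  n >= 4L && substr(trna$seq, n - 2L, n) == "CCA"
}

#' Check for an intact 3'-CCA terminus
#'
#' The universal single-stranded CCA end (canonical 74-76) is required for
#' aminoacylation.
#'
#' @param trna a `trna` (or any object with a `seq` field of length >= 4).
#' @return `TRUE` iff the last three residues are C, C, A.
#' @export
check_cca <- function(trna) {
  n <- nchar(trna$seq)
  if (n < 4L)
    stop("sequence too short (", n, " nt) to carry a discriminator + CCA end")
  substr(trna$seq, n - 2L, n) == "CCA"
}
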