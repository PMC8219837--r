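# Secondary-structure representation and the canonical cloverleaf target.

#' Parse a dot-bracket string
#'
#' Stack matching of `(`/`)` over `.`; pseudoknots cannot be expressed, so
#' pairs are nested by construction. Enforces the minimum hairpin loop of 3
#' unpaired residues (every pair satisfies j - i >= 4).
#'
#' @param s dot-bracket string over `(`, `)`, `.`.
#' @return a `secondary_structure`: `dotbracket`, `pairs` (2-column integer
#'   matrix, i < j, 1-based), `length`.
#' @examples
#' ss <- parse_dotbracket("(((....)))")
#' ss$pairs
#' @export
parse_dotbracket <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  ch <- strsplit(s, "")[[1]]
  bad <- which(!ch %in% c("(", ")", "."))
  if (length(bad))
    stop("invalid character '", ch[bad[1]], "' at position ", bad[1])
  open <- integer(0)
  pairs <- matrix(integer(0), ncol = 2)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") open <- c(open, i)
    else if (ch[i] == ")") {
      if (!length(open))
        stop("unbalanced ')' at position ", i)
      j <- open[length(open)]
      open <- open[-length(open)]
      if (i - j < 4L)
        stop("hairpin loop shorter than 3 closed by pair (", j, ",", i, ")")
      pairs <- rbind(pairs, c(j, i))
    }
  }
  if (length(open))
    stop("unbalanced '(' at position ", open[length(open)])
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  structure(list(dotbracket = s, pairs = pairs, length = length(ch)),
            class = "secondary_structure")
}

#' Render a secondary structure back to its dot-bracket string
#' @param ss a `secondary_structure`.
#' @return dot-bracket string (round-trips with [parse_dotbracket()]).
#' @export
write_dotbracket <- function(ss) {
  ch <- rep(".", ss$length)
  ch[ss$pairs[, 1]] <- "("
  ch[ss$pairs[, 2]] <- ")"
  paste(ch, collapse = "")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat("secondary_structure (", x$length, " nt, ", nrow(x$pairs),
      " pairs)\n", x$dotbracket, "\n", sep = "")
  invisible(x)
}

#' Pair table of a secondary structure
#' @param ss a `secondary_structure`.
#' @return integer vector: partner index per position, 0 if unpaired.
#' @export
pair_table <- function(ss) {
  pt <- integer(ss$length)
  pt[ss$pairs[, 1]] <- ss$pairs[, 2]
  pt[ss$pairs[, 2]] <- ss$pairs[, 1]
  pt
}

as_structure <- function(x, n = NULL) {
  if (inherits(x, "secondary_structure")) x else parse_dotbracket(x)
}

#' The canonical 76-nt cloverleaf target structure
#'
#' Four helices of 7 (acceptor), 4 (D), 5 (anticodon) and 5 (T) pairs; loop
#' sizes 8 (D), 7 (anticodon), 5 (variable), 7 (T) and a 4-nt 3' tail. The
#' helix/loop layout matches [arm_segments()]: acceptor pairs 1-72 ... 7-66,
#' D pairs 10-25 ... 13-22, anticodon pairs 27-43 ... 31-39, T pairs
#' 49-65 ... 53-61.
#'
#' @return a `cloverleaf_target`: `structure` (a `secondary_structure`) and
#'   `arms` ([arm_segments()]).
#' @export
cloverleaf_target <- function() {
  if (!is.null(.trnadesign_env$cloverleaf)) return(.trnadesign_env$cloverleaf)
  arms <- arm_segments()
  ch <- rep(".", 76)
  for (st in arms$stems) {
    ch[as.integer(st[, 1])] <- "("
    ch[as.integer(st[, 2])] <- ")"
  }
  out <- structure(list(structure = parse_dotbracket(paste(ch, collapse = "")),
                        arms = arms),
                   class = "cloverleaf_target")
  .trnadesign_env$cloverleaf <- out
  out
}

#' @export
print.cloverleaf_target <- function(x, ...) {
  cat("cloverleaf target (76 nt, 21 pairs):\n", x$structure$dotbracket, "\n",
      sep = "")
  invisible(x)
}

# Conserved tertiary interactions of the unmodified E. coli tRNA(Phe)
# cloverleaf core, as base-identity requirements at canonical labels:
# base triples, base pairs, and single bases engaged in calculated hydrogen
# bonds. Entries touching CORE_ONLY_LABELS are enforced only in "full" mode
# (the most-constrained designs); "core" mode drops them.
CORE_ONLY_LABELS <- c("15", "18", "48", "54", "55", "57", "58", "59", "60")

tertiary_catalogue <- function() {
  tri <- function(...) list(kind = "triple", ...)
  pr  <- function(...) list(kind = "pair", ...)
  hb  <- function(...) list(kind = "hbond", ...)
  list(
    tri(labels = c("8", "14", "21"),  bases = c("U", "A", "A")),
    tri(labels = c("9", "12", "23"),  bases = c("A", "U", "A")),
    tri(labels = c("10", "25", "44"), bases = c("G", "C", "G")),
    tri(labels = c("13", "22", "46"), bases = c("C", "G", "G")),
    pr(labels = c("15", "48"), bases = c("G", "C")),
    pr(labels = c("18", "55"), bases = c("G", "U")),
    pr(labels = c("19", "56"), bases = c("G", "C")),
    pr(labels = c("54", "58"), bases = c("U", "A")),
    hb(labels = "11", bases = "C"),
    hb(labels = "24", bases = "G"),
    hb(labels = "57", bases = "G"),
    hb(labels = "59", bases = "U"),
    hb(labels = "60", bases = "U"))
}

#' Tertiary-contact catalogue
#'
#' The conserved tertiary interactions used as design restraints: 4 base
#' triples, 4 base pairs and 5 hydrogen-bonding bases. `full` returns all 13
#' entries; `core` drops every entry involving a label in the
#' full-designs-only set \{15, 18, 48, 54, 55, 57, 58, 59, 60\}.
#'
#' @param mode `"full"` or `"core"`.
#' @return a `tertiary_contacts` object (list of entries with `kind`,
#'   `labels`, `bases`).
#' @export
tertiary_contacts <- function(mode = c("full", "core")) {
  mode <- match.arg(mode)
  entries <- tertiary_catalogue()
  if (mode == "core")
    entries <- Filter(function(e) !any(e$labels %in% CORE_ONLY_LABELS),
                      entries)
  structure(entries, class = "tertiary_contacts", mode = mode)
}

#' @export
print.tertiary_contacts <- function(x, ...) {
  cat("tertiary contacts (", attr(x, "mode"), " mode, ", length(x),
      " entries)\n", sep = "")
  for (e in x)
    cat(" ", e$kind, ": ",
        paste0(e$bases, e$labels, collapse = "-"), "\n", sep = "")
  invisible(x)
}

#' Fraction of tertiary contacts satisfied by a sequence
#'
#' A contact is satisfied iff every base identity it names is present at its
#' canonical label. Labels absent from the tRNA's numbering count as
#' violations (reason "absent position"). An empty contact set scores 1 by
#' convention.
#'
#' @param trna a `trna`.
#' @param contacts a `tertiary_contacts` object.
#' @return list with `fraction`, `satisfied`, `total` and a `violations`
#'   data frame (contact, reason).
#' @export
contact_compliance <- function(trna, contacts) {
  total <- length(contacts)
  if (total == 0L)
    return(list(fraction = 1, satisfied = 0L, total = 0L,
                violations = data.frame(contact = character(0),
                                        reason = character(0))))
  ok <- logical(total)
  reason <- character(total)
  for (i in seq_len(total)) {
    e <- contacts[[i]]
    if (!all(e$labels %in% names(trna$numbering$index_of))) {
      ok[i] <- FALSE
      reason[i] <- "absent position"
    } else {
      ok[i] <- all(base_at(trna, e$labels) == e$bases)
      if (!ok[i]) reason[i] <- "base mismatch"
    }
  }
  label_of <- vapply(contacts, function(e)
    paste0(e$kind, ":", paste0(e$bases, e$labels, collapse = "-")), "")
  list(fraction = sum(ok) / total, satisfied = sum(ok), total = total,
       violations = data.frame(contact = label_of[!ok],
                               reason = reason[!ok]))
}
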