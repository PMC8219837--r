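# Rational tRNA-editing grammar: anticodon swap, acceptor/anticodon-stem
# pair substitutions, TPsiC-stem and D-arm transplants, variable-loop
# extension; plus the additive elongation-factor affinity score and the
# validation report. Every edit changes only its declared canonical labels.

#' Swap the anticodon (canonical labels 34-36)
#'
#' Replaces the three anticodon residues 5'->3'; nothing else changes, so
#' the Hamming distance to the input is at most 3. The anticodon pairs
#' antiparallel with the codon (e.g. UCA reads the UGA stop codon: A36 with
#' U, C35 with G, U34 with A).
#'
#' @param trna a `trna`.
#' @param new_ac 3-mer over A/C/G/U.
#' @return the edited `trna`.
#' @export
swap_anticodon <- function(trna, new_ac) {
  new_ac <- normalize_rna(new_ac)
  if (nchar(new_ac) != 3L) stop("anticodon must be a 3-mer")
  replace_at(trna, as.character(34:36), strsplit(new_ac, "")[[1]])
}

# pairs eligible for substitute_pair: the cloverleaf stems plus the
# loop-closing 32-38 interaction of the anticodon loop
substitutable_pairs <- function() {
  arms <- arm_segments()
  pr <- do.call(rbind, arms$stems)
  rbind(pr, c("32", "38"))
}

#' Substitute a base pair at two canonical labels
#'
#' The two labels must form a cloverleaf stem pair (e.g. the acceptor-stem
#' 7-66 repair, the anticodon-stem closure 31-39) or the loop-closing
#' 32-38 interaction. Exactly two residues change.
#'
#' @param trna a `trna`.
#' @param label_i,label_j canonical labels of the pair (5' and 3' side).
#' @param new_pair two bases, as "GC" or c("G", "C").
#' @param force allow a non-pairing base combination.
#' @return the edited `trna`.
#' @export
substitute_pair <- function(trna, label_i, label_j, new_pair,
                            force = FALSE) {
  label_i <- as.character(label_i); label_j <- as.character(label_j)
  new_pair <- strsplit(normalize_rna(paste(new_pair, collapse = "")),
                       "")[[1]]
  if (length(new_pair) != 2L) stop("new_pair must supply exactly 2 bases")
  sp <- substitutable_pairs()
  if (!any(sp[, 1] == label_i & sp[, 2] == label_j))
    stop("(", label_i, ",", label_j,
         ") is not a cloverleaf stem pair or the 32-38 loop closure")
  if (!force && !is_allowed_pair(new_pair[1], new_pair[2]))
    stop(new_pair[1], "·", new_pair[2],
         " is not an allowed pair (use force = TRUE to override)")
  replace_at(trna, c(label_i, label_j), new_pair)
}

transplant_labels <- function(region) {
  switch(region,
    t_stem = as.character(c(49:53, 61:65)),
    d_arm  = as.character(10:25),
    stop("unknown transplant region '", region,
         "'; expected t_stem or d_arm"))
}

transplant_stem_pairs <- function(region) {
  arms <- arm_segments()
  if (region == "t_stem") arms$stems$t_stem else arms$stems$d_stem
}

#' Transplant a donor region into a tRNA
#'
#' Replaces the TPsiC-stem (10 residues at labels 49-53 and 61-65, e.g. a
#' donor stem from a strong elongation-factor binder) or the D-arm (16
#' residues at labels 10-25, D-stem plus D-loop) with donor residues given
#' in 5'->3' label order. Donor stem complementarity is validated; only the
#' region's labels change. A D-arm transplant can relax at most the
#' 9-12-23 base triple among the tertiary contacts of a previously fully
#' compliant tRNA (label 12 is the only contact position inside labels
#' 10-25 whose identity the transplant may rewrite via the donor D-loop
#' signature; see [contact_compliance()]).
#'
#' @param trna a `trna`.
#' @param region `"t_stem"` or `"d_arm"`.
#' @param donor RNA string with one residue per region label.
#' @return the edited `trna`.
#' @export
transplant <- function(trna, region, donor) {
  labels <- transplant_labels(region)
  donor <- normalize_rna(donor)
  if (nchar(donor) != length(labels))
    stop(region, " transplant needs ", length(labels),
         " residues, got ", nchar(donor))
  db <- strsplit(donor, "")[[1]]
  names(db) <- labels
  for (r in seq_len(nrow(transplant_stem_pairs(region)))) {
    pp <- transplant_stem_pairs(region)[r, ]
    if (!is_allowed_pair(db[[pp[1]]], db[[pp[2]]]))
      stop("donor stem pair ", pp[1], "-", pp[2], " (", db[[pp[1]]], "·",
           db[[pp[2]]], ") cannot pair")
  }
  out <- replace_at(trna, labels, unname(db))
  if (region == "d_arm") {
    # re-validate: a D-arm signature is expected to relax at most the
    # 9-12-23 base triple; flag any further newly violated contact
    contacts <- tertiary_contacts("full")
    before <- contact_compliance(trna, contacts)$violations$contact
    after <- contact_compliance(out, contacts)$violations$contact
    new_viol <- setdiff(after, before)
    unexpected <- new_viol[!grepl("9-U12-A23", new_viol)]
    if (length(unexpected))
      warning("d_arm transplant newly violates contact(s) beyond the ",
              "9-12-23 triple: ", paste(unexpected, collapse = ", "))
  }
  out
}

#' Extend the variable loop
#'
#' Inserts residues after canonical label 47 (new labels 47a, 47b, ...),
#' regenerating the numbering; all other labels, the anticodon included,
#' keep their positions in canonical coordinates.
#'
#' @param trna a `trna` with standard numbering.
#' @param insert RNA string to insert (length >= 1 unless `allow_noop`).
#' @param allow_noop permit an empty insert (returns the input unchanged).
#' @return the extended `trna`.
#' @export
extend_variable <- function(trna, insert, allow_noop = FALSE) {
  insert <- if (nchar(insert) == 0) "" else normalize_rna(insert)
  if (nchar(insert) == 0) {
    if (allow_noop) return(trna)
    stop("empty variable-loop insert (set allow_noop = TRUE to permit)")
  }
  i47 <- label_index(trna$numbering, "47") + trna$numbering$insertions
  n_new <- nchar(trna$seq) + nchar(insert)
  trna$seq <- paste0(substr(trna$seq, 1, i47), insert,
                     substr(trna$seq, i47 + 1, nchar(trna$seq)))
  trna$numbering <- canonical_map(n_new, n_new - 76L)
  trna
}

#' Read a per-base-pair affinity contribution table
#'
#' TSV with columns `pair` (stem position pair, e.g. "49-65"), `bases`
#' (pair identity written 5' side first, e.g. "GC") and `ddG` (kcal/mol
#' contribution to elongation-factor binding). Comment lines (`#`) carry
#' provenance. No literature values are bundled: tables citing measured
#' contributions are supplied by the user.
#'
#' @param path TSV path.
#' @return a `contribution_table` data frame with a `provenance` attribute.
#' @export
read_contrib_table <- function(path) {
  lines <- readLines(path)
  prov <- sub("^#\\s*", "", lines[grepl("^#", lines)])
  df <- utils::read.delim(text = lines[!grepl("^#", lines)],
                          stringsAsFactors = FALSE)
  need <- c("pair", "bases", "ddG")
  if (!all(need %in% names(df)))
    stop("contribution table must have columns: ",
         paste(need, collapse = ", "))
  structure(df[need], provenance = paste(prov, collapse = " "),
            class = c("contribution_table", "data.frame"))
}

#' Additive elongation-factor binding-affinity score
#'
#' Sums the table's per-base-pair contributions for the tRNA's actual base
#' pairs at the listed stem position pairs (the TPsiC-stem pairs 49-65,
#' 50-64 and 51-63 carry the strongest influence on EF-Tu binding). Pairs
#' listed in the table but with no entry matching the tRNA's bases score 0
#' and are reported as unscored; an empty table scores 0.
#'
#' @param trna a `trna`.
#' @param table a [read_contrib_table()] result (or compatible data frame).
#' @return list with `score` (kcal/mol), `scored` (data frame of matched
#'   entries) and `unscored` (position pairs defaulted to 0).
#' @export
eftu_score <- function(trna, table) {
  if (nrow(table) == 0)
    return(list(score = 0,
                scored = data.frame(pair = character(0),
                                    bases = character(0), ddG = numeric(0)),
                unscored = character(0)))
  pairs <- unique(table$pair)
  scored <- table[0, , drop = FALSE]
  unscored <- character(0)
  total <- 0
  for (p in pairs) {
    lb <- strsplit(p, "-")[[1]]
    have <- paste(base_at(trna, lb), collapse = "")
    hit <- table[table$pair == p & table$bases == have, , drop = FALSE]
    if (nrow(hit)) {
      total <- total + hit$ddG[1]
      scored <- rbind(scored, hit[1, ])
    } else unscored <- c(unscored, p)
  }
  list(score = total, scored = scored, unscored = unscored)
}

#' Validate a tRNA against the design checks
#'
#' Pure report aggregating the sequence-level checks: intact CCA end,
#' the G3.U70 AlaRS identity element, all identity-provenance restraints,
#' the equilibrium cloverleaf probability P(S), the MFE structure, and the
#' tertiary-contact compliance fraction for the restraint set's mode.
#'
#' @param trna a `trna`.
#' @param model an [energy_model()].
#' @param restraints a `restraint_set` (defines the identity positions and
#'   contact mode checked).
#' @return a `validation_report` list.
#' @export
validate_trna <- function(trna, model = default_energy_model(),
                          restraints = build_restraints("CUA", "full")) {
  cca_ok <- check_cca(trna)
  g3u70_ok <- identical(unname(base_at(trna, c("3", "70"))), c("G", "U"))
  id_labels <- names(restraints$fixed)[restraints$provenance == "identity"]
  id_hit <- base_at(trna, id_labels) == unname(restraints$fixed[id_labels])
  target <- restraints$target$structure
  p <- if (nchar(trna$seq) == 76)
    suppressWarnings(probability_of(trna$seq, target, model)) else NA_real_
  fr <- mfe(trna$seq, model)
  cc <- contact_compliance(trna, tertiary_contacts(restraints$mode))
  structure(list(
    id = trna$id,
    cca_ok = cca_ok,
    g3u70_ok = g3u70_ok,
    identity_ok = all(id_hit),
    identity_detail = data.frame(label = id_labels,
                                 required = unname(restraints$fixed[id_labels]),
                                 found = base_at(trna, id_labels),
                                 ok = id_hit),
    p_cloverleaf = p,
    mfe_energy = fr$mfe_energy,
    mfe_structure = fr$mfe_structure$dotbracket,
    contact_fraction = cc$fraction,
    contact_violations = cc$violations,
    pass = cca_ok && g3u70_ok && all(id_hit),
    warn = !is.na(p) && p < 0.01),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("validation_report for ", x$id, ": ",
      if (x$pass) "PASS" else "FAIL", if (x$warn) " (warn: low P(S))",
      "\n  cca_ok=", x$cca_ok, " g3u70_ok=", x$g3u70_ok,
      " identity_ok=", x$identity_ok,
      "\n  P(cloverleaf)=", format(x$p_cloverleaf, digits = 4),
      "  MFE=", format(x$mfe_energy, digits = 4),
      "  contacts=", format(x$contact_fraction, digits = 3), "\n", sep = "")
  invisible(x)
}

# --- edit recipes -----------------------------------------------------------

#' Read an edit recipe (YAML)
#'
#' A recipe is a named, ordered list of primitive edits applied
#' left-to-right. Supported ops: `swap_anticodon` (`ac`), `substitute_pair`
#' (`i`, `j`, `bases`), `transplant` (`region`, `donor`), `extend_variable`
#' (`insert`).
#'
#' @param path YAML file with fields `name` and `ops`.
#' @return an `edit_recipe`.
#' @export
read_recipe <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$ops)) stop("recipe has no 'ops' list")
  structure(list(name = y$name %||% basename(path), ops = y$ops),
            class = "edit_recipe")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply an edit recipe to a tRNA
#' @param trna a `trna`.
#' @param recipe an `edit_recipe` (or a bare list of ops).
#' @return the edited `trna`.
#' @export
apply_recipe <- function(trna, recipe) {
  ops <- if (inherits(recipe, "edit_recipe")) recipe$ops else recipe
  for (op in ops) {
    trna <- switch(op$op,
      swap_anticodon  = swap_anticodon(trna, op$ac),
      substitute_pair = substitute_pair(trna, op$i, op$j, op$bases,
                                        force = isTRUE(op$force)),
      transplant      = transplant(trna, op$region, op$donor),
      extend_variable = extend_variable(trna, op$insert),
      stop("unknown recipe op '", op$op, "'"))
  }
  trna
}
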