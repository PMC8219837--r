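# Folding thermodynamics: structure energy, equilibrium partition function,
# target-structure probability, and MFE folding.

MAX_FOLD_LEN <- 200L

check_fold_input <- function(seq) {
  n <- nchar(seq)
  if (n < 1L || n > MAX_FOLD_LEN)
    stop("sequence length ", n, " outside supported range 1..", MAX_FOLD_LEN)
  n
}

#' Free energy of a sequence in a given secondary structure
#'
#' Deterministic loop decomposition under the nearest-neighbor model: the
#' open chain is the 0 kcal/mol reference state; each pair contributes the
#' hairpin, stack/bulge/internal or multiloop term of the loop it closes.
#'
#' @param seq RNA string.
#' @param structure dot-bracket string or `secondary_structure` of the same
#'   length.
#' @param model an [energy_model()].
#' @return energy in kcal/mol.
#' @export
rna_energy <- function(seq, structure, model = default_energy_model()) {
  seq <- normalize_rna(seq)
  ss <- as_structure(structure)
  if (ss$length != nchar(seq))
    stop("structure length ", ss$length, " != sequence length ", nchar(seq))
  res <- c_energy(seq_codes(seq), pair_table(ss), cpar(model))
  if (is.na(res$energy)) {
    i <- res$bad_i; j <- res$bad_j
    stop("incompatible pair at (", i, ",", j, "): ",
         substr(seq, i, i), "·", substr(seq, j, j),
         " is not an allowed pair")
  }
  res$energy
}

#' Equilibrium partition function
#'
#' Boltzmann-weighted sum Z over all pseudoknot-free secondary structures
#' with minimum hairpin loop 3 (the open chain contributes exp(0) = 1, so
#' Z >= 1), computed by O(n^3) dynamic programming; interior loops are
#' capped at the model's `maxloop` unpaired residues. Per-nucleotide
#' rescaling (`qscale`) guards against overflow; the result is
#' scale-independent.
#'
#' @param seq RNA string (1..200 nt).
#' @param model an [energy_model()].
#' @param log if `TRUE` return log Z.
#' @param qscale per-nucleotide scaling factor (default 1).
#' @return Z (or log Z).
#' @export
partition_function <- function(seq, model = default_energy_model(),
                               log = FALSE, qscale = 1) {
  seq <- normalize_rna(seq)
  check_fold_input(seq)
  lz <- c_partition(seq_codes(seq), cpar(model), model$RT, qscale)
  if (log) lz else exp(lz)
}

prob_quiet <- function(codes, target_pt, par, RT) {
  e <- c_energy(codes, target_pt, par)
  if (is.na(e$energy)) return(list(p = 0, logp = -Inf, incompatible = TRUE,
                                   bad = c(e$bad_i, e$bad_j)))
  lz <- c_partition(codes, par, RT, 1)
  lp <- -e$energy / RT - lz
  list(p = min(exp(lp), 1), logp = min(lp, 0), incompatible = FALSE,
       energy = e$energy, logZ = lz)
}

#' Equilibrium probability of a target structure
#'
#' P(S) = exp(-E(S)/RT) / Z, the Boltzmann probability that the sequence
#' adopts exactly the target structure. If the target demands a disallowed
#' pair (possible for partially optimized design candidates), the
#' probability is 0 and a structured warning of class
#' `trnadesign_incompatible_target` is raised.
#'
#' @param seq RNA string.
#' @param target dot-bracket string or `secondary_structure`.
#' @param model an [energy_model()].
#' @return probability in \[0, 1\] (positive whenever the target is
#'   compatible).
#' @export
probability_of <- function(seq, target, model = default_energy_model()) {
  seq <- normalize_rna(seq)
  check_fold_input(seq)
  ss <- as_structure(target)
  if (ss$length != nchar(seq))
    stop("target length ", ss$length, " != sequence length ", nchar(seq))
  res <- prob_quiet(seq_codes(seq), pair_table(ss), cpar(model), model$RT)
  if (res$incompatible) {
    warning(structure(class = c("trnadesign_incompatible_target", "warning",
                                "condition"),
                      list(message = paste0(
                        "target pair (", res$bad[1], ",", res$bad[2],
                        ") not formable by this sequence; P(S) = 0"),
                        call = sys.call())))
    return(0)
  }
  res$p
}

#' Minimum-free-energy fold
#'
#' Dynamic-programming MFE structure under the same loop decomposition as
#' [partition_function()], with a deterministic traceback (ties resolve to
#' the first candidate in a fixed scan order: hairpin, then interior loops
#' by ascending inner pair, then multiloop splits; exterior bases prefer to
#' stay unpaired).
#'
#' @param seq RNA string.
#' @param model an [energy_model()].
#' @return a `fold_result`: `mfe_structure`, `mfe_energy` (kcal/mol), `Z`,
#'   `logZ`, and `p_target` (the equilibrium probability of the MFE
#'   structure itself).
#' @export
mfe <- function(seq, model = default_energy_model()) {
  seq <- normalize_rna(seq)
  check_fold_input(seq)
  codes <- seq_codes(seq)
  par <- cpar(model)
  res <- c_mfe(codes, par)
  pt <- res$ptab
  ch <- rep(".", length(pt))
  ch[pt > seq_along(pt)] <- "("
  ch[pt != 0 & pt < seq_along(pt)] <- ")"
  ss <- parse_dotbracket(paste(ch, collapse = ""))
  lz <- c_partition(codes, par, model$RT, 1)
  structure(list(mfe_structure = ss, mfe_energy = res$energy,
                 logZ = lz, Z = exp(lz),
                 p_target = min(exp(-res$energy / model$RT - lz), 1)),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat("fold_result: MFE ", format(x$mfe_energy, digits = 4),
      " kcal/mol, P(MFE) = ", format(x$p_target, digits = 4), "\n",
      x$mfe_structure$dotbracket, "\n", sep = "")
  invisible(x)
}
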