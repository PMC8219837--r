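# Constrained sequence design: restraint assembly and stochastic
# optimization of candidate suppressor tRNAs ranked by the equilibrium
# probability of the cloverleaf target, P(S).

#' Assemble a fixed-nucleotide restraint set
#'
#' Union of the AlaRS aminoacylation identity elements (G1-G4, G20 and the
#' 3' block C69 U70 C71 C72 A73 C74 C75 A76, which fixes the G3.U70 wobble
#' identity element and the CCA end), the conserved tertiary-interaction
#' bases at their canonical labels ([tertiary_contacts()], `full` or `core`
#' per `mode`), the requested anticodon at labels 34-36, and any extra
#' user-fixed positions. Conflicting assignments to a label are an error
#' naming the label.
#'
#' @param anticodon 3-mer over A/C/G/U (e.g. "CUA" to decode UAG, "UCA" for
#'   UGA).
#' @param mode `"full"` or `"core"` tertiary restraints.
#' @param extra_fixed optional named character vector, canonical label ->
#'   base.
#' @return a `restraint_set`: `fixed` (named base vector), `provenance`
#'   (named tag vector: identity/tertiary/anticodon/user), `target`
#'   ([cloverleaf_target()]), `mode`, `anticodon`.
#' @examples
#' rs <- build_restraints("CUA", "full")
#' render_restraints(rs)
#' @export
build_restraints <- function(anticodon = "CUA", mode = c("full", "core"),
                             extra_fixed = NULL) {
  mode <- match.arg(mode)
  anticodon <- normalize_rna(anticodon)
  if (nchar(anticodon) != 3L)
    stop("anticodon must be a 3-mer, got '", anticodon, "'")
  fixed <- character(0)
  prov <- character(0)
  add <- function(labels, bases, tag) {
    for (k in seq_along(labels)) {
      lb <- labels[k]; b <- bases[k]
      if (lb %in% names(fixed) && fixed[[lb]] != b)
        stop("conflicting restraints at canonical label ", lb, ": ",
             fixed[[lb]], " (", prov[[lb]], ") vs ", b, " (", tag, ")")
      fixed[[lb]] <<- b
      if (!lb %in% names(prov)) prov[[lb]] <<- tag
    }
  }
  idm <- alars_identity_map()
  add(names(idm), unname(idm), "identity")
  for (e in tertiary_contacts(mode)) add(e$labels, e$bases, "tertiary")
  add(as.character(34:36), strsplit(anticodon, "")[[1]], "anticodon")
  if (!is.null(extra_fixed)) {
    add(names(extra_fixed),
        vapply(unname(extra_fixed), normalize_rna, ""), "user")
  }
  ord <- order(as.integer(names(fixed)))
  structure(list(fixed = fixed[ord], provenance = prov[ord],
                 target = cloverleaf_target(), mode = mode,
                 anticodon = anticodon),
            class = "restraint_set")
}

#' Render a restraint set as a 76-character template row
#'
#' Fixed bases at their canonical positions, dots at free positions.
#'
#' @param restraints a `restraint_set`.
#' @return character scalar of length 76.
#' @export
render_restraints <- function(restraints) {
  ch <- rep(".", 76)
  ch[as.integer(names(restraints$fixed))] <- unname(restraints$fixed)
  paste(ch, collapse = "")
}

#' @export
print.restraint_set <- function(x, ...) {
  cat("restraint_set (", x$mode, " mode, anticodon ", x$anticodon, ", ",
      length(x$fixed), " fixed / ", 76 - length(x$fixed),
      " free positions)\n", render_restraints(x), "\n", sep = "")
  invisible(x)
}

free_positions <- function(restraints) {
  setdiff(1:76, as.integer(names(restraints$fixed)))
}

#' Draw random restraint-conforming sequences
#'
#' Fixed labels take their required base; free positions are i.i.d. uniform
#' over A/C/G/U. Uses the current R RNG state (seed with [set.seed()] for
#' reproducibility).
#'
#' @param restraints a `restraint_set`.
#' @param n number of sequences.
#' @return character vector of 76-nt sequences.
#' @export
random_conforming <- function(restraints, n = 1L) {
  free <- free_positions(restraints)
  tmpl <- rep(NA_character_, 76)
  tmpl[as.integer(names(restraints$fixed))] <- unname(restraints$fixed)
  vapply(seq_len(n), function(i) {
    tmpl[free] <- sample(RNA_BASES, length(free), replace = TRUE)
    paste(tmpl, collapse = "")
  }, "")
}

#' Design-run configuration
#'
#' @param n_candidates independent optimization runs per design
#'   (default 10000).
#' @param top_k sequences retained after ranking (default 5).
#' @param iterations annealing moves per candidate (default 150).
#' @param t_start,t_end initial/final annealing temperatures on the
#'   log-probability scale (geometric cooling).
#' @param move_pair_prob probability of proposing a joint complementary
#'   substitution at a free target stem pair instead of a single-base move.
#' @param seed master seed; per-candidate sub-seeds are derived by counter.
#' @return a `design_config` list.
#' @export
design_config <- function(n_candidates = 10000L, top_k = 5L,
                          iterations = 150L, t_start = 2, t_end = 0.05,
                          move_pair_prob = 0.5, seed = 1L) {
  stopifnot(n_candidates >= 1L, top_k >= 1L, top_k <= n_candidates,
            iterations >= 0L, t_start > 0, t_end > 0)
  structure(list(n_candidates = as.integer(n_candidates),
                 top_k = as.integer(top_k),
                 iterations = as.integer(iterations),
                 t_start = t_start, t_end = t_end,
                 move_pair_prob = move_pair_prob,
                 seed = as.integer(seed)),
            class = "design_config")
}

# Objective: log P(target) when every target pair is formable; otherwise a
# large negative score improving with each additional formable pair, so the
# search can cross the infeasible region that uniform random initialization
# of free stem positions usually starts in.
design_objective <- function(codes, target_pt, par, RT) {
  res <- prob_quiet(codes, target_pt, par, RT)
  if (res$incompatible) {
    pi <- which(target_pt > seq_along(target_pt))
    ptype <- matrix(0L, 4, 4)
    ptype[cbind(c(1, 2, 3, 3, 4, 4), c(4, 3, 2, 4, 1, 3))] <- 1L
    nbad <- sum(ptype[cbind(codes[pi] + 1L, codes[target_pt[pi]] + 1L)] == 0L)
    list(value = -1000 * nbad, p = 0, logp = -Inf)
  } else list(value = res$logp, p = res$p, logp = res$logp)
}

#' Optimize a single restraint-conforming candidate
#'
#' Simulated annealing over the free positions, maximizing log P(S) of the
#' cloverleaf target. Moves: single free-position substitution, or (with
#' probability `move_pair_prob` when available) a joint complementary
#' substitution at a target stem pair whose two positions are both free.
#' Geometric cooling from `t_start` to `t_end`; the best-so-far sequence is
#' returned with its exactly recomputed P(S) (never a search-internal
#' value).
#'
#' @param restraints a `restraint_set`.
#' @param model an [energy_model()].
#' @param config a [design_config()].
#' @param seed integer sub-seed for this run.
#' @return a `design_candidate`: `seq`, `p_target`, `logp`, `objective`,
#'   `restraint_ok`, `sub_seed`.
#' @export
optimize_one <- function(restraints, model = default_energy_model(),
                         config = design_config(), seed = 1L) {
  set.seed(seed)
  par <- cpar(model)
  RT <- model$RT
  target_pt <- pair_table(restraints$target$structure)
  free <- free_positions(restraints)
  base_codes <- 0:3
  cur <- seq_codes(random_conforming(restraints, 1L))
  # free target stem pairs eligible for joint complementary moves
  pr <- restraints$target$structure$pairs
  pair_free <- pr[pr[, 1] %in% free & pr[, 2] %in% free, , drop = FALSE]
  pair_codes <- rbind(c(0L, 3L), c(1L, 2L), c(2L, 1L), c(2L, 3L),
                      c(3L, 0L), c(3L, 2L))
  obj <- design_objective(cur, target_pt, par, RT)
  best <- cur; best_obj <- obj
  it <- config$iterations
  if (it > 0 && length(free) > 0) {
    temps <- config$t_start *
      (config$t_end / config$t_start)^(seq_len(it) / it)
    for (step in seq_len(it)) {
      cand <- cur
      if (nrow(pair_free) > 0 && runif(1) < config$move_pair_prob) {
        k <- pair_free[sample.int(nrow(pair_free), 1L), ]
        nc <- pair_codes[sample.int(6L, 1L), ]
        cand[k[1]] <- nc[1]; cand[k[2]] <- nc[2]
      } else {
        p <- free[sample.int(length(free), 1L)]
        cand[p] <- sample(setdiff(base_codes, cur[p]), 1L)
      }
      cand_obj <- design_objective(cand, target_pt, par, RT)
      d <- cand_obj$value - obj$value
      if (d >= 0 || runif(1) < exp(d / temps[step])) {
        cur <- cand; obj <- cand_obj
        if (obj$value > best_obj$value) { best <- cur; best_obj <- obj }
      }
    }
  }
  seq <- paste(RNA_BASES[best + 1L], collapse = "")
  final <- prob_quiet(best, target_pt, par, RT)
  structure(list(seq = seq, p_target = final$p, logp = final$logp,
                 objective = best_obj$value,
                 restraint_ok = conforms(seq, restraints),
                 sub_seed = as.integer(seed)),
            class = "design_candidate")
}

#' Does a sequence satisfy every fixed-position restraint?
#' @param seq 76-nt RNA string.
#' @param restraints a `restraint_set`.
#' @return logical.
#' @export
conforms <- function(seq, restraints) {
  ch <- strsplit(seq, "")[[1]]
  all(ch[as.integer(names(restraints$fixed))] == unname(restraints$fixed))
}

sub_seed_for <- function(master, i) {
  as.integer((as.numeric(master) + 1000003 * i) %% 2147483647)
}

#' Run the candidate-design pipeline
#'
#' Runs [optimize_one()] `n_candidates` times with counter-derived
#' sub-seeds, ranks all candidates by P(S) descending (ties broken
#' lexicographically on sequence), collapses duplicate sequences into one
#' record with a multiplicity count, and retains the `top_k` leaders
#' alongside the full score table.
#'
#' @param restraints a `restraint_set`.
#' @param model an [energy_model()].
#' @param config a [design_config()].
#' @return a `design_result`: `candidates` (full ranked data frame with
#'   columns rank, id, sequence, p_target, mfe_energy, restraint_ok,
#'   multiplicity, sub_seed), `top` (first `top_k` rows), `n_emitted`,
#'   `config`, `restraints`, `model_checksum`.
#' @export
design_pipeline <- function(restraints, model = default_energy_model(),
                            config = design_config()) {
  n <- config$n_candidates
  cands <- vector("list", n)
  for (i in seq_len(n))
    cands[[i]] <- optimize_one(restraints, model, config,
                               seed = sub_seed_for(config$seed, i))
  df <- data.frame(
    sequence = vapply(cands, `[[`, "", "seq"),
    p_target = vapply(cands, `[[`, 0, "p_target"),
    restraint_ok = vapply(cands, `[[`, TRUE, "restraint_ok"),
    sub_seed = vapply(cands, `[[`, 1L, "sub_seed"))
  stopifnot(all(df$restraint_ok))
  # collapse duplicates, keep the earliest sub-seed as provenance
  agg <- split(seq_len(n), df$sequence)
  keep <- vapply(agg, `[`, 1L, 1L)
  mult <- vapply(agg, length, 1L)
  df <- df[keep, , drop = FALSE]
  df$multiplicity <- as.integer(mult)
  ord <- order(-df$p_target, df$sequence)
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  df$id <- sprintf("d%04d", df$rank)
  df$mfe_energy <- vapply(df$sequence,
                          function(s) mfe(s, model)$mfe_energy, 0,
                          USE.NAMES = FALSE)
  df <- df[, c("rank", "id", "sequence", "p_target", "mfe_energy",
               "restraint_ok", "multiplicity", "sub_seed")]
  rownames(df) <- NULL
  structure(list(candidates = df, top = head(df, config$top_k),
                 n_emitted = n, config = config, restraints = restraints,
                 model_checksum = model$checksum),
            class = "design_result")
}

#' @export
print.design_result <- function(x, ...) {
  cat("design_result:", x$n_emitted, "candidates emitted,",
      nrow(x$candidates), "unique; top", nrow(x$top), "by P(cloverleaf):\n")
  print(x$top[, c("rank", "id", "p_target", "mfe_energy")], row.names = FALSE)
  invisible(x)
}
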