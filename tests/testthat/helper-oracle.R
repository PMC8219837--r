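# Independent brute-force oracle for the folding thermodynamics: exhaustive
# enumeration of all pseudoknot-free structures (min hairpin 3) and a plain-R
# re-implementation of the loop-decomposition energy, written against the R
# model object and kept separate from the package's compiled routines.

ORACLE_PAIRS <- c("AU", "UA", "CG", "GC", "GU", "UG")

# all structures of seq as 2-column pair matrices (includes the open chain)
enum_structures <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  can_pair <- function(a, b) paste0(ch[a], ch[b]) %in% ORACLE_PAIRS
  memo <- new.env(parent = emptyenv())
  empty <- matrix(integer(0), ncol = 2)
  rec <- function(i, j) {
    if (j - i < 4) return(list(empty))
    key <- paste0(i, ":", j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- rec(i + 1, j)                       # i unpaired
    for (k in (i + 4):j) {
      if (!can_pair(i, k)) next
      for (a in rec(i + 1, k - 1))
        for (b in if (k < j) rec(k + 1, j) else list(empty))
          out[[length(out) + 1]] <- rbind(c(i, k), a, b)
    }
    memo[[key]] <- out
    out
  }
  rec(1, n)
}

oracle_loop_tab <- function(tab, size, lxc) {
  mx <- max(as.integer(names(tab)))
  if (size <= mx) unname(tab[[as.character(size)]])
  else unname(tab[[as.character(mx)]]) + lxc * log(size / mx)
}

oracle_energy <- function(seq, pairs, model) {
  if (nrow(pairs) == 0) return(0)
  ch <- strsplit(seq, "")[[1]]
  pt <- integer(length(ch))
  pt[pairs[, 1]] <- pairs[, 2]
  pt[pairs[, 2]] <- pairs[, 1]
  E <- 0
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    kids <- list(); unp <- 0; k <- i + 1
    while (k < j) {
      if (pt[k] > k) { kids[[length(kids) + 1]] <- c(k, pt[k]); k <- pt[k] + 1 }
      else { unp <- unp + 1; k <- k + 1 }
    }
    if (length(kids) == 0) {
      E <- E + oracle_loop_tab(model$hairpin, j - i - 1, model$lxc)
    } else if (length(kids) == 1) {
      kk <- kids[[1]]
      n1 <- kk[1] - i - 1; n2 <- j - kk[2] - 1
      if (n1 == 0 && n2 == 0)
        E <- E + model$stack[paste0(ch[i], ch[j]), paste0(ch[kk[1]], ch[kk[2]])]
      else if (n1 == 0 || n2 == 0)
        E <- E + oracle_loop_tab(model$bulge, n1 + n2, model$lxc)
      else
        E <- E + oracle_loop_tab(model$internal, n1 + n2, model$lxc) +
          min(model$asym_max, model$asym * abs(n1 - n2))
    } else {
      E <- E + model$ml_closing + model$ml_branch * (length(kids) + 1) +
        model$ml_unpaired * unp
    }
  }
  E
}

oracle_boltzmann <- function(seq, model) {
  structs <- enum_structures(seq)
  energies <- vapply(structs, function(p) oracle_energy(seq, p, model), 0)
  list(structures = structs, energies = energies,
       Z = sum(exp(-energies / model$RT)))
}

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                       replace = TRUE), collapse = "")
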