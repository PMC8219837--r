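test_that("structure energy follows the loop decomposition", {
  # open chain is the reference state
  expect_identical(rna_energy("ACGUACGUA", "........."), 0)
  # two GC/GC stacks (-3.26 each) + size-4 hairpin (+5.6), from the
  # shipped parameter table
  expect_equal(rna_energy("GGGAAAACCC", "(((....)))"), -0.92)
  # disallowed pair is an error naming the offending pair
  expect_error(rna_energy("AAAAAAAA", "((....))"), "A·A")
  expect_error(rna_energy("GGGAAAACCC", "((....))"), "length")
})

test_that("partition function handles pairless and short sequences", {
  expect_equal(partition_function("AAAA"), 1)
  expect_equal(partition_function("GC"), 1)
  expect_gte(partition_function("GGGGCCCC"), 1)
  for (s in c("GCGC", "AUAU", "GGCC"))  # < 5 nt: hairpin rule forbids pairs
    expect_equal(partition_function(s), 1)
})

test_that("Z, E and P agree with exhaustive enumeration on random RNAs", {
  model <- default_energy_model()
  set.seed(101)
  for (rep in 1:30) {
    s <- random_rna(sample(8:15, 1))
    orc <- oracle_boltzmann(s, model)
    expect_equal(partition_function(s, model), orc$Z,
                 tolerance = 1e-9)
    # pick a few non-trivial structures: E and P must match the oracle
    idx <- which(vapply(orc$structures, nrow, 1L) > 0)
    for (k in head(idx, 3)) {
      pairs <- orc$structures[[k]]
      pt <- integer(nchar(s))
      pt[pairs[, 1]] <- pairs[, 2]; pt[pairs[, 2]] <- pairs[, 1]
      ch <- rep(".", nchar(s))
      ch[pairs[, 1]] <- "("; ch[pairs[, 2]] <- ")"
      db <- paste(ch, collapse = "")
      expect_equal(rna_energy(s, db, model), orc$energies[k],
                   tolerance = 1e-9)
      expect_equal(probability_of(s, db, model),
                   exp(-orc$energies[k] / model$RT) / orc$Z,
                   tolerance = 1e-9)
    }
  }
})

test_that("structure probabilities are normalized and two-state exact", {
  model <- default_energy_model()
  set.seed(7)
  for (rep in 1:5) {
    s <- random_rna(12)
    orc <- oracle_boltzmann(s, model)
    p <- exp(-orc$energies / model$RT) / partition_function(s, model)
    expect_equal(sum(p), 1, tolerance = 1e-9)
  }
  # a sequence with exactly one structure besides the open chain:
  # p = w / (1 + w) with w = exp(-E/RT)
  s2 <- "GAAAAC"
  orc2 <- oracle_boltzmann(s2, model)
  expect_identical(length(orc2$structures), 2L)
  E <- rna_energy(s2, "(....)", model)
  w <- exp(-E / model$RT)
  expect_equal(probability_of(s2, "(....)", model), w / (1 + w),
               tolerance = 1e-12)
  expect_equal(probability_of("AAAA", "....", model), 1)
})

test_that("P(S) tends to the uniform distribution at high temperature", {
  set.seed(19)
  hot <- energy_model(temperature = 1e9)
  for (rep in 1:3) {
    s <- random_rna(12)
    n_structs <- length(enum_structures(s))
    expect_equal(partition_function(s, hot), n_structs, tolerance = 1e-4)
    expect_equal(probability_of(s, strrep(".", 12), hot), 1 / n_structs,
                 tolerance = 1e-4)
  }
})

test_that("incompatible targets give probability 0 with a typed warning", {
  expect_warning(p <- probability_of("AAAAAAAAAA", "(((....)))"),
                 class = "trnadesign_incompatible_target")
  expect_identical(p, 0)
})

test_that("MFE structure is optimal and consistent with the ensemble", {
  model <- default_energy_model()
  f0 <- mfe("AAAA")
  expect_identical(f0$mfe_energy, 0)
  expect_identical(f0$mfe_structure$dotbracket, "....")
  f1 <- mfe("GGGGAAAACCCC")
  expect_lt(f1$mfe_energy, 0)
  expect_gt(nrow(f1$mfe_structure$pairs), 0)
  set.seed(33)
  for (rep in 1:12) {
    s <- random_rna(sample(10:15, 1))
    orc <- oracle_boltzmann(s, model)
    fr <- mfe(s, model)
    expect_equal(fr$mfe_energy, min(orc$energies), tolerance = 1e-9)
    # traceback structure realizes the MFE energy exactly
    expect_equal(rna_energy(s, fr$mfe_structure$dotbracket, model),
                 fr$mfe_energy, tolerance = 1e-9)
    # no single structure beats the MFE structure's probability
    pmax_oracle <- exp(-min(orc$energies) / model$RT) / orc$Z
    expect_equal(fr$p_target, pmax_oracle, tolerance = 1e-9)
  }
})

test_that("partition function is stable under per-step rescaling at 76 nt", {
  set.seed(5)
  s <- random_conforming(full_restraints(), 1)
  z1 <- partition_function(s, log = TRUE, qscale = 1)
  for (sc in c(0.8, 1.2, 2)) {
    z2 <- partition_function(s, log = TRUE, qscale = sc)
    expect_equal(z2, z1, tolerance = 1e-6)
  }
})

test_that("fold input validation rejects out-of-range lengths", {
  expect_error(partition_function(strrep("A", 201)), "outside supported")
  expect_error(rna_energy("ACGN", "...."), "N")
})
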