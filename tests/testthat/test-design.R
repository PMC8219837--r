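test_that("build_restraints reproduces the combined design template", {
  rs <- build_restraints("CUA", "full")
  expect_identical(render_restraints(rs),
                   unname(table1_rows()[["combined"]]))
  # UCA anticodon: identical except labels 34-36
  rs_uca <- build_restraints("UCA", "full")
  a <- strsplit(render_restraints(rs), "")[[1]]
  b <- strsplit(render_restraints(rs_uca), "")[[1]]
  expect_identical(which(a != b), 34:35)  # third anticodon base A is shared
  expect_identical(b[34:36], c("U", "C", "A"))
  expect_identical(a[-(34:36)], b[-(34:36)])
})

test_that("identity and anticodon rows agree with their templates", {
  rs <- build_restraints("CUA", "full")
  idl <- names(rs$fixed)[rs$provenance == "identity"]
  ch <- strsplit(table1_rows()[["alars_identity"]], "")[[1]]
  expect_setequal(which(ch != "."), as.integer(idl))
  expect_identical(ch[as.integer(idl)], unname(rs$fixed[idl]))
  acr <- strsplit(table1_rows()[["new_anticodon"]], "")[[1]]
  expect_identical(which(acr != "."), 34:36)
  expect_identical(acr[34:36], c("C", "U", "A"))
})

test_that("core mode leaves the full-design-only positions free", {
  rs <- build_restraints("CUA", "core")
  free <- setdiff(as.character(1:76), names(rs$fixed))
  expect_true(all(c("15", "18", "48", "54", "55", "57", "58", "59", "60")
                  %in% free))
  expect_true(all(c("19", "56", "11", "24") %in% names(rs$fixed)))
})

test_that("restraint conflicts and bad anticodons are rejected", {
  expect_error(build_restraints("CU", "full"), "3-mer")
  expect_error(build_restraints("CUA", "full",
                                extra_fixed = c(`3` = "A")),
               "conflicting restraints at canonical label 3")
  # a compatible duplicate is not a conflict
  rs <- build_restraints("CUA", "full", extra_fixed = c(`3` = "G", `5` = "A"))
  expect_identical(unname(rs$fixed[["5"]]), "A")
  expect_identical(unname(rs$provenance[["5"]]), "user")
})

test_that("random_conforming honors fixed positions and the RNG contract", {
  rs <- full_restraints()
  set.seed(3)
  seqs <- random_conforming(rs, 200)
  expect_true(all(vapply(seqs, conforms, TRUE, restraints = rs)))
  expect_true(all(nchar(seqs) == 76))
  set.seed(3)
  expect_identical(random_conforming(rs, 200), seqs)
  # all-fixed restraints admit exactly one sequence
  rs_all <- build_restraints("CUA", "full",
    extra_fixed = structure(rep("A", 76 - length(rs$fixed)),
                            names = setdiff(as.character(1:76),
                                            names(rs$fixed))))
  expect_identical(length(unique(random_conforming(rs_all, 5))), 1L)
})

test_that("optimize_one meets its contracts", {
  rs <- full_restraints()
  model <- default_energy_model()
  # zero iterations return the initialization
  cfg0 <- design_config(n_candidates = 1, top_k = 1, iterations = 0)
  c0 <- optimize_one(rs, model, cfg0, seed = 11)
  set.seed(11)
  expect_identical(c0$seq, random_conforming(rs, 1))
  # all positions fixed: the unique conforming sequence comes back with its
  # exact probability
  free <- setdiff(as.character(1:76), names(rs$fixed))
  rs_all <- build_restraints("CUA", "full",
    extra_fixed = structure(rep("A", length(free)), names = free))
  ca <- optimize_one(rs_all, model,
                     design_config(n_candidates = 1, top_k = 1,
                                   iterations = 5), seed = 2)
  expect_identical(ca$seq, random_conforming(rs_all, 1))
  expect_equal(ca$p_target,
               suppressWarnings(probability_of(
                 ca$seq, cloverleaf_target()$structure, model)))
  # optimization never ends below its own initialization
  cfg <- design_config(n_candidates = 1, top_k = 1, iterations = 60)
  for (seed in c(5, 23)) {
    opt <- optimize_one(rs, model, cfg, seed = seed)
    set.seed(seed)
    init_p <- suppressWarnings(probability_of(
      random_conforming(rs, 1), cloverleaf_target()$structure, model))
    expect_gte(opt$p_target, init_p)
    expect_true(opt$restraint_ok)
  }
})

test_that("design_pipeline ranks, deduplicates and reproduces", {
  rs <- full_restraints()
  cfg <- design_config(n_candidates = 24, top_k = 5, iterations = 30,
                       seed = 9)
  res <- design_pipeline(rs, config = cfg)
  df <- res$candidates
  expect_identical(res$n_emitted, 24L)
  expect_identical(sum(df$multiplicity), 24L)
  expect_identical(df$rank, seq_len(nrow(df)))
  expect_true(all(diff(df$p_target) <= 0))
  expect_true(all(df$restraint_ok))
  expect_true(all(vapply(df$sequence, conforms, TRUE, restraints = rs)))
  expect_identical(nrow(res$top), 5L)
  # same seed => identical result; different seed => different candidates
  res2 <- design_pipeline(rs, config = cfg)
  expect_identical(res$candidates, res2$candidates)
  res3 <- design_pipeline(rs, config = design_config(n_candidates = 24,
                                                     top_k = 5,
                                                     iterations = 30,
                                                     seed = 10))
  expect_false(identical(res$candidates$sequence, res3$candidates$sequence))
})

test_that("all-fixed restraints collapse the pipeline to one record", {
  rs <- full_restraints()
  free <- setdiff(as.character(1:76), names(rs$fixed))
  rs_all <- build_restraints("CUA", "full",
    extra_fixed = structure(rep("A", length(free)), names = free))
  res <- design_pipeline(rs_all, config = design_config(n_candidates = 8,
                                                        top_k = 1,
                                                        iterations = 0,
                                                        seed = 4))
  expect_identical(nrow(res$candidates), 1L)
  expect_identical(res$candidates$multiplicity, 8L)
})
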