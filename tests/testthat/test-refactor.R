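hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

test_that("swap_anticodon touches only labels 34-36", {
  t <- ref_trna()
  t2 <- swap_anticodon(t, "UCA")
  expect_identical(segment(t2, "anticodon")$seq, "UCA")
  expect_lte(hamming(t$seq, t2$seq), 3)
  diffs <- which(strsplit(t$seq, "")[[1]] != strsplit(t2$seq, "")[[1]])
  expect_true(all(diffs %in% 34:36))
  # swapping to the current anticodon is the identity
  expect_identical(swap_anticodon(t, "CUA")$seq, t$seq)
  expect_error(swap_anticodon(t, "UCAG"), "3-mer")
})

test_that("substitute_pair edits exactly one stem pair", {
  t <- ref_trna()
  t <- trnadesign:::replace_at(t, c("7", "66"), c("C", "G"))  # give it the C7-G66 state
  t2 <- substitute_pair(t, 7, 66, "GC")          # acceptor-stem repair
  expect_identical(unname(base_at(t2, c("7", "66"))), c("G", "C"))
  expect_identical(hamming(t$seq, t2$seq), 2L)
  t3 <- substitute_pair(t, 31, 39, "CG")         # anticodon-loop closure
  expect_identical(unname(base_at(t3, c("31", "39"))), c("C", "G"))
  t4 <- substitute_pair(t, 32, 38, "UA")         # loop-closing 32-38
  expect_identical(unname(base_at(t4, c("32", "38"))), c("U", "A"))
  expect_error(substitute_pair(t, 31, 39, "AA"), "not an allowed pair")
  expect_identical(unname(base_at(
    substitute_pair(t, 31, 39, "AA", force = TRUE), c("31", "39"))),
    c("A", "A"))
  expect_error(substitute_pair(t, 14, 21, "GC"), "not a cloverleaf stem")
})

test_that("transplants replace exactly their region", {
  t <- ref_trna()
  # a strong-binder style T-stem changes exactly the 10 stem positions
  donor <- "GGGGGCCCCC"  # pairs 49-65..53-61 all G-C
  t2 <- transplant(t, "t_stem", donor)
  # transplanting a tRNA's own (pairing) region is the identity
  own_t <- segment(t2, "t_arm")$seq
  donor_own <- paste0(substr(own_t, 1, 5), substr(own_t, 13, 17))
  expect_identical(transplant(t2, "t_stem", donor_own)$seq, t2$seq)
  diffs <- which(strsplit(t$seq, "")[[1]] != strsplit(t2$seq, "")[[1]])
  expect_true(all(diffs %in% c(49:53, 61:65)))
  expect_identical(paste(base_at(t2, as.character(c(49:53, 61:65))),
                         collapse = ""), donor)
  expect_error(transplant(t, "t_stem", "GGGG"), "10 residues")
  expect_error(transplant(t, "t_stem", "GGGGGCCCCA"), "cannot pair")
  expect_error(transplant(t, "elbow", "GGGG"), "unknown transplant region")
})

test_that("a D-arm signature relaxes at most the 9-12-23 triple", {
  t <- ref_trna()
  full <- tertiary_contacts("full")
  expect_identical(contact_compliance(t, full)$fraction, 1)
  # donor: the tRNA's own D-arm with the 12-23 pair rewritten U-A -> C-G
  own <- strsplit(segment(t, "d_arm")$seq, "")[[1]]  # labels 8..25
  donor <- own[3:18]                                 # labels 10..25
  donor[3] <- "C"; donor[14] <- "G"                  # labels 12 and 23
  t2 <- transplant(t, "d_arm", paste(donor, collapse = ""))
  diffs <- which(strsplit(t$seq, "")[[1]] != strsplit(t2$seq, "")[[1]])
  expect_true(all(diffs %in% 10:25))
  cc <- contact_compliance(t2, full)
  expect_equal(cc$fraction, 12 / 13)
  expect_match(cc$violations$contact, "A9-U12-A23")
  # a donor clobbering an unrelated contact is flagged on re-validation
  bad <- own[3:18]
  bad[5] <- "C"; bad[12] <- "G"  # labels 14 and 21: breaks the 8-14-21 triple
  expect_warning(transplant(t, "d_arm", paste(bad, collapse = "")),
                 "beyond the 9-12-23 triple")
})

test_that("variable-loop extension regenerates the numbering", {
  t <- ref_trna()
  t2 <- extend_variable(t, "GCGAU")
  expect_identical(nchar(t2$seq), 81L)
  expect_identical(t2$numbering$insertions, 5L)
  expect_true(all(c("47a", "47e") %in% names(t2$numbering$index_of)))
  # anticodon and every other canonical label keep their residues
  for (lb in c("34", "35", "36", "47", "48", "76"))
    expect_identical(base_at(t2, lb), base_at(t, lb))
  expect_identical(paste(base_at(t2, paste0("47", letters[1:5])),
                         collapse = ""), "GCGAU")
  expect_error(extend_variable(t, ""), "empty variable-loop insert")
  expect_identical(extend_variable(t, "", allow_noop = TRUE)$seq, t$seq)
})

test_that("recipes compose left-to-right", {
  t <- ref_trna()
  ops <- list(list(op = "swap_anticodon", ac = "UCA"),
              list(op = "substitute_pair", i = 31, j = 39, bases = "CG"),
              list(op = "extend_variable", insert = "AAG"))
  stepwise <- extend_variable(
    substitute_pair(swap_anticodon(t, "UCA"), 31, 39, "CG"), "AAG")
  expect_identical(apply_recipe(t, ops)$seq, stepwise$seq)
  # YAML round trip
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(name = "demo", ops = ops), path)
  rec <- read_recipe(path)
  expect_identical(rec$name, "demo")
  expect_identical(apply_recipe(t, rec)$seq, stepwise$seq)
})

test_that("eftu_score is additive and local", {
  t <- ref_trna()
  empty <- data.frame(pair = character(0), bases = character(0),
                      ddG = numeric(0))
  expect_identical(eftu_score(t, empty)$score, 0)
  p4965 <- paste(base_at(t, c("49", "65")), collapse = "")
  p5064 <- paste(base_at(t, c("50", "64")), collapse = "")
  tab1 <- data.frame(pair = "49-65", bases = p4965, ddG = -1.3)
  tab2 <- data.frame(pair = "50-64", bases = p5064, ddG = 0.7)
  expect_equal(eftu_score(t, tab1)$score, -1.3)
  both <- rbind(tab1, tab2)
  expect_equal(eftu_score(t, both)$score,
               eftu_score(t, tab1)$score + eftu_score(t, tab2)$score)
  # non-matching base identity defaults to 0 and is reported
  miss <- data.frame(pair = "51-63", bases = "XX", ddG = -9)
  sc <- eftu_score(t, miss)
  expect_identical(sc$score, 0)
  expect_identical(sc$unscored, "51-63")
  # positions outside the table's labels cannot move the score
  t_far <- swap_anticodon(t, "UCA")
  expect_identical(eftu_score(t_far, both)$score, eftu_score(t, both)$score)
})

test_that("validate_trna reports the design checks and is pure", {
  t <- ref_trna()
  before <- t$seq
  rep1 <- validate_trna(t)
  expect_identical(t$seq, before)
  expect_true(rep1$cca_ok)
  expect_true(rep1$g3u70_ok)
  expect_true(rep1$identity_ok)
  expect_identical(rep1$contact_fraction, 1)
  t2 <- trnadesign:::replace_at(t, "70", "C")
  rep2 <- validate_trna(t2)
  expect_false(rep2$g3u70_ok)
  expect_false(rep2$identity_ok)
  expect_false(rep2$pass)
})
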