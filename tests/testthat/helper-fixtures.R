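# Shared test fixtures, built in code.

# a random restraint-conforming 76-nt tRNA: satisfies every fixed position
# of the combined template (identity + full tertiary + CUA anticodon)
ref_trna <- function(seed = 42) {
  set.seed(seed)
  rs <- build_restraints("CUA", "full")
  trna(random_conforming(rs, 1), id = paste0("ref_seed", seed))
}

full_restraints <- function() build_restraints("CUA", "full")
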