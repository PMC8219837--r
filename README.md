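# trnadesign

De novo design and rational editing of nonsense suppressor tRNAs.

Premature stop codons (UAA, UAG, UGA) truncate proteins and underlie many
genetic diseases. A *suppressor tRNA* reads such a stop codon as a sense
codon so that translation continues. This package is for RNA engineers and
structural bioinformaticians who want to build such suppressors
computationally: it designs tRNA bodies from scratch under fixed-nucleotide
restraints and provides the rational editing operations used to tune them
(anticodon retargeting, TΨC-stem and D-arm surgery, variable-loop
extension, acceptor-stem pair repairs), with automatic re-validation.

## The model

A candidate tRNA is a 76-nt sequence in canonical tRNA numbering
(anticodon 34–36, CCA end 74–76, variable-loop insertions 47a, 47b, …).
Designs are constrained by three restraint classes, assembled by
`build_restraints()`:

* **aminoacylation identity elements** of alanyl-tRNA synthetase (AlaRS),
  centered in the acceptor stem and independent of the anticodon — notably
  the G3·U70 wobble pair;
* **conserved tertiary interactions** of the cloverleaf core — base triples
  (U8·A14·A21, A9·U12·A23, G10·C25·G44, C13·G22·G46), base pairs (G15·C48,
  G18·U55, G19·C56, U54·A58) and hydrogen-bonding bases (C11, G24, G57,
  U59, U60) — applied in a `full` or a relaxed `core` mode;
* the **anticodon**, e.g. CUA to decode UAG or UCA to decode UGA.

Free positions are optimized so that the sequence folds into the canonical
cloverleaf secondary structure S (acceptor stem 7 bp, D-stem 4 bp,
anticodon stem 5 bp, T-stem 5 bp). The objective is the equilibrium
probability of that structure,

    P(S) = exp(−E(S)/RT) / Z,    Z = Σ_S' exp(−E(S')/RT),

where E is a nearest-neighbor free energy and Z the full partition function
over all pseudoknot-free structures (McCaskill-style O(n³) dynamic
programming, implemented in C++ with an exhaustive-enumeration oracle in
the test suite). Each design run draws `n_candidates` (default 10,000)
independent simulated-annealing searches over the free positions and ranks
candidates by P(S); the top `top_k` (default 5) are retained.

For tuning existing tRNAs, `eftu_score()` computes the additive per-base-
pair contribution of the TΨC-stem (pairs 49–65, 50–64, 51–63 dominate) to
elongation-factor binding affinity from a user-supplied contribution table.

## Worked example

Design UGA suppressors (small run for illustration) and validate the top
candidate:

```r
library(trnadesign)

rs <- build_restraints("UCA", "full")
rs
#> restraint_set (full mode, anticodon UCA, 41 fixed / 35 free positions)
#> GGGG...UAGCUCAG..GGGAGAGC........UCA.......G.G.C.....UUCGAUU........CUCCACCA

res <- design_pipeline(rs, config = design_config(n_candidates = 200,
                                                  top_k = 3, seed = 7))
res
#> design_result: 200 candidates emitted, 200 unique; top 3 by P(cloverleaf):
#>  rank    id  p_target mfe_energy
#>     1 d0001 0.7865359     -19.55
#>     2 d0002 0.6977948     -19.47
#>     3 d0003 0.6802221     -19.54

best <- trna(res$top$sequence[1], id = res$top$id[1])
validate_trna(best, restraints = rs)
#> validation_report for d0001: PASS
#>   cca_ok=TRUE g3u70_ok=TRUE identity_ok=TRUE
#>   P(cloverleaf)=0.7865  MFE=-19.55  contacts=1
```

The template row shows every fixed nucleotide (dots are free). The top
candidate folds into the cloverleaf with equilibrium probability 0.79,
carries an intact CCA end and the G3·U70 identity element, and satisfies
all 13 tertiary-contact identities (`contacts=1`).

The same workflows are available from the shell via the thin CLI in
`exec/trnadesign` (`design`, `fold`, `edit`, `validate`, `score-eftu`,
`fixtures`), e.g.

```sh
trnadesign design --anticodon UCA --mode full -n 10000 -k 5 --seed 42 \
    -o report.tsv --fasta top.fa
```

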