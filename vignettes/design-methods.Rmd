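---
title: "Designing nonsense suppressor tRNAs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing nonsense suppressor tRNAs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the science it implements:
the coordinate system, the thermodynamic model behind the ranking score,
the constrained optimizer, the editing grammar, and the numerical and
design choices a maintainer should know about.

## The problem

A nonsense suppressor tRNA decodes a stop codon so that translation reads
through instead of terminating. Building one computationally means
searching sequence space for a 76-nt RNA that (i) carries the fixed
nucleotides that a real tRNA needs — aminoacylation identity elements for
its synthetase, the conserved tertiary-interaction bases that lock the
L-shaped fold, and the desired anticodon — and (ii) among all sequences
satisfying those restraints, folds as reliably as possible into the
canonical cloverleaf secondary structure.

```{r}
library(trnadesign)
build_restraints("CUA", "full")
```

The template above fixes 41 of 76 positions: the AlaRS identity block
(G1–G4, G20, C69–A76 including the G3·U70 wobble pair and the CCA end),
the tertiary-interaction bases, and the anticodon. `core` mode drops the
nine tertiary positions {15, 18, 48, 54, 55, 57, 58, 59, 60} that only the
most-constrained designs enforce, freeing them for optimization.

## Canonical coordinates

Canonical labels 1–76 follow the standard tRNA convention (anticodon
34–36, tail 73–76); variable-loop insertions are labeled 47a, 47b, … in
insertion order, a common convention for extended V-loops. Labels are
1-based to match the field's notation (G3–U70, pairs 49–65). Sequence
indices are ordinary 1-based R indices — not 0-based as a
language-agnostic description might use — because every R container and
every installed sequence package indexes from 1; the mapping between
labels and indices lives entirely in the `canonical_numbering` object, so
no other code performs coordinate arithmetic. Arm regions partition the
labels exactly: the connector residues 8–9 are counted with the D-arm and
26 with the anticodon arm, which makes region concatenation reconstruct
the full sequence — a property the test suite checks.

Lengths other than 76 + insertions are accepted only with an explicit
numbering, since nothing in a bare sequence says which positions are
missing or duplicated.

## The thermodynamic model

The ranking score is the equilibrium probability of the cloverleaf target
\(S\):

\[ P(S) = \frac{e^{-E(S)/RT}}{Z}, \qquad
   Z = \sum_{S'} e^{-E(S')/RT} , \]

with the sum over all pseudoknot-free secondary structures with a minimum
hairpin loop of 3 unpaired residues. \(Z\) is computed by the standard
McCaskill-style \(O(n^3)\) inside recursion (compiled C++), \(E\) by loop
decomposition, and the MFE structure by the matching minimization with
traceback.

The energy model is a compact nearest-neighbor parameter set shipped as a
versioned, sectioned TSV (`inst/extdata/energy_params.tsv`, kcal/mol at
37 °C): a full 6×6 stacking table for the allowed pairs (AU, UA, CG, GC,
GU, UG) obeying the thermodynamic symmetry
\(E(ab/cd) = E(dc/ba)\); hairpin, internal and bulge initiation penalties
by loop size with Jacobson–Stockmayer extrapolation
\(E(n) = E(n_{\max}) + 1.079\,\ln(n/n_{\max})\) beyond the tables;
Ninio-style internal-loop asymmetry (0.6 kcal/mol per unpaired-length
difference, capped at 3.0); and an affine multiloop cost (closing 3.4,
per branch 0.4, per unpaired base 0.1). Deliberate simplifications, noted
in the parameter file header: no dangling ends, no coaxial stacking, no
terminal-pair penalties, no modified-base energetics, and lonely pairs are
permitted. The model is pluggable — `energy_model(path)` loads any file in
the same format — so a richer parameter set can be substituted without
touching the algorithms.

Defaults that matter:

* temperature 310.15 K (37 °C, the physiological working temperature),
  with \(R = 1.98717\times10^{-3}\) kcal/(mol·K); configurable via
  `energy_model(temperature = )`.
* interior loops capped at 30 unpaired residues inside the DP (standard
  practice; irrelevant at tRNA scale).
* sequence length capped at 200 nt — the package targets tRNAs, not
  genomes.

### Numerical choices

* The partition function supports per-nucleotide rescaling (`qscale`) as
  an overflow guard; at tRNA lengths doubles never overflow, and the test
  suite checks that scaled and unscaled runs agree to \(10^{-6}\)
  relative at 76 nt.
* MFE traceback ties resolve deterministically by a fixed scan order
  (hairpin first, then interior loops by ascending inner pair, then
  multiloop splits; exterior bases prefer to stay unpaired), so reruns are
  byte-identical.
* Degenerate inputs: sequences shorter than 5 nt have \(Z = 1\) (the
  hairpin rule forbids all pairs); the open chain is the 0 kcal/mol
  reference state; a target demanding a pair the sequence cannot form
  yields \(P(S) = 0\) with a typed warning rather than an error, because
  partially optimized design candidates legitimately pass through such
  states.
* Correctness is anchored by a brute-force oracle
  (`tests/testthat/helper-oracle.R`): exhaustive structure enumeration
  plus an independent plain-R energy implementation. On random sequences
  up to 18 nt, \(Z\), \(E\) and \(P\) agree with enumeration to
  \(10^{-9}\) relative error, ensemble probabilities sum to 1, and at
  very high temperature \(P\) tends to the uniform distribution — so the
  dynamic programs provably sum over exactly the intended structure
  space.

## The optimizer

The published workflows this package follows used an external
inverse-folding optimizer whose internals are not described alongside the
pipeline contract; the contract itself — generate `n_candidates`
restraint-conforming sequences, rank by \(P(S)\), keep the top `top_k` —
is what the package preserves. The packaged optimizer is simulated
annealing, chosen because it is simple, self-contained, seedable, and
directly optimizes the exact reported objective:

* state: the free positions (fixed positions never move);
* moves: a single-base substitution at a random free position, or, with
  probability 0.5 when the target pairs two free positions, a joint
  substitution of a random allowed pair type at that stem pair (stem
  moves repair pairing much faster than independent point moves);
* objective: \(\log P(S)\). A uniformly random start usually violates
  some target pairs, making \(P(S) = 0\); the objective then falls back
  to \(-1000\times(\text{number of unformable target pairs})\), a ramp
  that leads the search into the feasible region, after which
  \(\log P(S)\) takes over;
* schedule: geometric cooling from `t_start = 2` to `t_end = 0.05` (units
  of log-probability) over `iterations = 150` moves — at roughly 3 ms per
  partition-function evaluation this keeps a 10,000-candidate run
  tractable while typically multiplying \(P(S)\) by orders of magnitude
  over the random start;
* the best-so-far sequence is returned, and its reported `p_target` is
  always a final exact recomputation, never a search-internal value.

Reproducibility: one master seed spawns per-candidate sub-seeds by
counter (`seed + 1000003·i mod 2^31−1`), each recorded in the report.
Ranking ties break lexicographically on the sequence, and duplicate
sequences collapse into one record with a multiplicity count — both
choices are arbitrary but documented, and fixed so that reports are
byte-stable.

## The editing grammar

Each operation changes only its declared canonical labels (checked by
diff in the tests):

* `swap_anticodon()` — labels 34–36, e.g. CUA (UAG) → UCA (UGA);
* `substitute_pair()` — one cloverleaf stem pair or the loop-closing
  32–38 interaction; non-pairing bases require `force = TRUE`. Typical
  uses: the acceptor-stem C7–G66 → G7–C66 repair, the C31–G39
  anticodon-loop closure, the U32–A38 pair;
* `transplant()` — the TΨC-stem (10 residues, labels 49–53/61–65; the
  route to stronger elongation-factor binding) or the D-arm (16 residues,
  labels 10–25). Donor stem complementarity is validated. A D-arm
  signature is expected to relax at most the A9·U12·A23 base triple
  (position 12 sits in the donor region and 23 is its stem partner); the
  operation re-checks tertiary compliance and warns if a donor clobbers
  anything beyond that triple;
* `extend_variable()` — inserts after label 47 (new labels 47a, 47b, …),
  regenerating the numbering so all other labels, the anticodon included,
  are untouched;
* recipes (YAML) compose these left-to-right; `apply_recipe()` equals the
  stepwise application.

`eftu_score()` implements the additive model of elongation-factor binding
affinity: the contribution of the TΨC-stem is the sum of independent
per-base-pair terms, dominated by pairs 49–65, 50–64 and 51–63. The
package bundles **no** literature values — measured contributions live in
the primary literature and differ by organism and factor — so the table
is user-supplied TSV; `inst/extdata/example_contrib_synthetic.tsv` is a
clearly marked invented placeholder for demos. Missing entries score 0
and are reported, keeping the score honest about its coverage.

`validate_trna()` aggregates the sequence-level checks a design must
pass: CCA end, G3·U70, all identity-element positions, \(P(S)\), the MFE
structure, and the tertiary-contact compliance fraction.

## What the random generator emulates — and what it does not

`random_conforming()` draws sequences that satisfy every fixed position,
with free positions i.i.d. uniform over A/C/G/U. It emulates the null
pool an unguided generator would produce under the same restraints, which
is exactly the baseline the optimizer must beat; the test suite and the
acceptance script compare median \(P(S)\) of optimized versus random
draws at n = 200 per arm. It does not emulate real tRNA sequence
composition (codon-usage or GC biases, covariation between stems), and
tertiary contacts are checked as base identities at canonical positions,
not as geometric hydrogen bonds — passing these tests therefore shows the
pipeline's internal consistency and the optimizer's effectiveness under
its own thermodynamic model, not that a designed sequence is
translationally competent in vivo.

## Scope limits and open choices

* Secondary structure only: no 3D modeling; the L-shaped fold is
  represented by the tertiary-identity restraints. Pseudoknots are
  rejected by construction.
* Post-transcriptional modifications are out of scope; T/Ψ-like input
  normalizes to U.
* The hydrogen-bonding bases C11, G24, G57, U59, U60 are modeled as
  identity-at-position requirements; their partners are not specified in
  the source material, so no pairwise geometry is asserted.
* The mid-sequence identity G is placed at canonical position 20, the
  position consistent with the combined template's spacing; an explicit
  donor numbering can override it via `extra_fixed`.
* Exact published designed sequences (and figure-only variant recipes)
  are not bundled: the recipe engine takes explicit donors rather than
  hard-coding sequence data the text does not print.
* Test problem sizes are chosen to keep the oracle exhaustive and the
  suite fast: enumeration up to 18 nt (hundreds of thousands of
  structures in total across 100 random sequences), pipeline contracts at
  n = 10,000 candidates with the iteration budget set to zero (the count,
  compliance and determinism contracts do not depend on the budget), and
  optimizer effectiveness at n = 200 per arm at the default budget.
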