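# Example edit recipe: retarget a designed UAG suppressor to UGA, stabilize
# the anticodon loop closure, and lengthen the variable loop.
name: uga_retarget_demo
ops:
  - op: swap_anticodon
    ac: UCA
  - op: substitute_pair
    i: 31
    j: 39
    bases: CG
  - op: extend_variable
    insert: GCGAU
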