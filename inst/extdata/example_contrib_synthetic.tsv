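# SYNTHETIC example contribution table for eftu_score(), for demos and tests
# only. Values are invented placeholders, NOT measured thermodynamic
# contributions; supply your own table citing the primary literature for any
# real analysis. Units: kcal/mol.
pair	bases	ddG
49-65	GC	-0.9
49-65	CG	-0.4
50-64	GC	-0.6
50-64	AU	0.3
51-63	CG	-0.5
51-63	UA	0.4
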