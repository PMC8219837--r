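# trnadesign nearest-neighbor energy parameters, v1
# Units: kcal/mol at 37 C. Allowed pairs: AU UA CG GC GU UG.
# Minimum hairpin loop = 3 unpaired residues; lonely (isolated) pairs permitted.
# No dangling ends, coaxial stacking or terminal-pair penalties (compact model).
# Loops larger than the tabulated maximum extrapolate as E(max) + lxc*ln(n/max).
# [stacks] rows: pair(i,j) pair(i+1,j-1) energy; pair written 5'base(i) then base(j).
[general]
lxc	1.079
maxloop	30
[stacks]
AU	AU	-0.93
AU	CG	-2.24
AU	GC	-2.08
AU	GU	-0.55
AU	UA	-1.10
AU	UG	-1.36
CG	AU	-2.11
CG	CG	-3.26
CG	GC	-2.36
CG	GU	-1.41
CG	UA	-2.08
CG	UG	-2.11
GC	AU	-2.35
GC	CG	-3.42
GC	GC	-3.26
GC	GU	-1.53
GC	UA	-2.24
GC	UG	-2.51
GU	AU	-1.27
GU	CG	-2.51
GU	GC	-2.11
GU	GU	-0.50
GU	UA	-1.36
GU	UG	0.47
UA	AU	-1.33
UA	CG	-2.35
UA	GC	-2.11
UA	GU	-1.00
UA	UA	-0.93
UA	UG	-1.27
UG	AU	-1.00
UG	CG	-1.53
UG	GC	-1.41
UG	GU	0.30
UG	UA	-0.55
UG	UG	-0.50
[hairpin]
3	5.40
4	5.60
5	5.70
6	5.40
7	6.00
8	5.50
9	6.40
10	6.51
11	6.62
12	6.71
13	6.80
14	6.88
15	6.95
16	7.02
17	7.09
18	7.15
19	7.21
20	7.26
21	7.31
22	7.36
23	7.41
24	7.46
25	7.50
26	7.54
27	7.59
28	7.62
29	7.66
30	7.70
[internal]
asym	0.60
asym_max	3.00
2	1.70
3	1.80
4	1.70
5	1.80
6	2.00
7	2.20
8	2.30
9	2.40
10	2.50
11	2.60
12	2.70
13	2.78
14	2.86
15	2.94
16	3.01
17	3.07
18	3.13
19	3.19
20	3.25
21	3.30
22	3.35
23	3.40
24	3.44
25	3.49
26	3.53
27	3.57
28	3.61
29	3.65
30	3.69
[bulge]
1	3.80
2	2.80
3	3.20
4	3.60
5	4.00
6	4.40
7	4.60
8	4.70
9	4.80
10	4.90
11	5.00
12	5.10
13	5.18
14	5.26
15	5.34
16	5.41
17	5.47
18	5.53
19	5.59
20	5.65
21	5.70
22	5.75
23	5.80
24	5.84
25	5.89
26	5.93
27	5.97
28	6.01
29	6.05
30	6.09
[multiloop]
closing	3.40
branch	0.40
unpaired	0.10
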