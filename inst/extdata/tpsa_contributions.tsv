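# Topological polar surface area atomic contributions, table version tpsa-1.
# Fragment-additive values (Angstrom^2) for nitrogen and oxygen environments,
# following the published fragment-contribution scheme for polar surface area.
# Matching: first row whose non-empty fields all equal the atom environment
# (element, aromatic, charge, hcount, n_single, n_double, n_triple, n_aromatic).
element	aromatic	charge	hcount	n_single	n_double	n_triple	n_aromatic	tpsa
N	0	0	0	3	0	0	0	3.24
N	0	0	0	1	1	0	0	12.36
N	0	0	0	0	0	1	0	23.79
N	0	0	0	1	2	0	0	11.68
N	0	0	1	2	0	0	0	12.03
N	0	0	1	0	1	0	0	23.85
N	0	0	2	1	0	0	0	26.02
N	1	0	0	0	0	0	2	12.89
N	1	0	0	1	0	0	2	4.93
N	1	0	0	0	0	0	3	4.41
N	1	0	1	0	0	0	2	15.79
N	0	1	0	4	0	0	0	0.00
N	0	1	0	2	1	0	0	3.01
N	0	1	1	3	0	0	0	4.44
N	0	1	2	2	0	0	0	16.61
N	0	1	3	1	0	0	0	27.64
N	1	1	1	0	0	0	2	14.14
N	1	1	0	1	0	0	2	3.01
N								3.24
O	0	0	0	2	0	0	0	9.23
O	0	0	1	1	0	0	0	20.23
O	0	0	0	0	1	0	0	17.07
O	1	0	0	0	0	0	2	13.14
O	0	-1	0	1	0	0	0	23.06
O								9.23
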