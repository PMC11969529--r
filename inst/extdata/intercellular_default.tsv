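metabolite	from	to	reversible	ub
glu	N	A	FALSE	0.05
gln	A	N	FALSE	0.04
gaba	N	A	FALSE	0.05
gly	N	A	TRUE	0.01
asp	N	A	TRUE	0.01
ala	N	A	TRUE	0.01
gln	A	M	FALSE	0.01
glu	N	M	FALSE	0.01
naa	N	O	FALSE	0.01
lac	N	shared	TRUE	0.05
lac	A	shared	TRUE	0.05
lac	M	shared	TRUE	0.05
lac	O	shared	TRUE	0.05
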