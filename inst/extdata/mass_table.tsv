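# Elemental compositions used by the molecular-weight calculator.
# kind=nucleoside rows give the full ribonucleoside formula (T is the
# 5-methyluridine ribonucleoside; the deoxy sugar delta converts it to dT).
# kind=delta rows are applied per residue (sugar chemistry) or per
# internucleotide linkage (bridge, ps). Negative counts mean atoms removed.
kind	key	C	H	N	O	P	F	S
nucleoside	A	10	13	5	4	0	0	0
nucleoside	C	9	13	3	5	0	0	0
nucleoside	G	10	13	5	5	0	0	0
nucleoside	U	9	12	2	6	0	0	0
nucleoside	T	10	14	2	6	0	0	0
delta	r	0	0	0	0	0	0	0
delta	m	1	2	0	0	0	0	0
delta	f	0	-1	0	-1	0	1	0
delta	d	0	0	0	-1	0	0	0
delta	bridge	0	-1	0	2	1	0	0
delta	ps	0	0	0	-1	0	0	1
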