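# Nearest-neighbor free energy parameters for Watson-Crick RNA/RNA helices.
# dg: Gibbs free energy increment, kcal/mol at 37 C (Xia et al. 1998 set).
# key: the dinucleotide step read 5'->3' on the top strand, paired to its
#      full Watson-Crick complement; values are rotationally symmetric
#      (dg(XY) == dg(reverse complement of XY)).
# "init" is the helix initiation term; "term_au" the per-end penalty for a
# terminal A-U pair.
key	dg
AA	-0.93
AC	-2.24
AG	-2.08
AU	-1.10
CA	-2.11
CC	-3.26
CG	-2.36
CU	-2.08
GA	-2.35
GC	-3.42
GG	-3.26
GU	-2.24
UA	-1.33
UC	-2.35
UG	-2.11
UU	-0.93
init	4.09
term_au	0.45
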