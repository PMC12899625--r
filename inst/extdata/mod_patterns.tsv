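# X/Y energy-class modification pattern table.
# X = low-energy monomer (A/U), Y = high-energy monomer (G/C).
# Cells give the per-position sugar assignment (m = 2'-O-methyl,
# f = 2'-fluoro) for each segment case; class letters in a cell are nominal
# and the actual strand's classes take precedence when they disagree
# (the sense-column cell for case 5'XY is reproduced verbatim from the
# source table even though its class letters read XX).
case	set1_even	set2_odd	sense
XXX	mXmXfX	mXfXmX	fXmXmX
YYY	mYmYfY	mYfYmY	fYmYmY
XYX	mXfYmX	fXmYfX	fXfYmX
YXY	fYmXfY	mYfXmY	mYmXfY
5'XY	mXfY	fXmY	fXfX
5'YX	mYfX	fYmX	fYfX
5'XX	mXmX	fXfX	mXfX
3'XY	mXfY	fXmY	mXfX
3'YX	fYmX	mYfX	mYmX
3'XX	fXfX	mXmX	fXmX
3'YY	mYmY	fYfY	fYmY
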