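# Loop penalties for the simplified minimum-free-energy folder (kcal/mol).
# Logarithmic loop-size extrapolation: penalty = base + log_coef * ln(n/ref).
# multiloop energy = ml_close + ml_branch per branch (closing pair included)
#                    + ml_unpaired per unpaired base in the loop.
name	value
hairpin_base	5.40
hairpin_ref	3
bulge_base	3.80
bulge_ref	1
internal_base	4.10
internal_ref	2
internal_asym	0.50
internal_asym_max	3.00
log_coef	1.078
ml_close	3.40
ml_branch	0.40
ml_unpaired	0.10
max_loop	30
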