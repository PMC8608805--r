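# Metabolizer phenotype cut-points on the diplotype activity score:
# a score s maps to the phenotype whose row satisfies lo < s <= hi.
gene	phenotype	lo	hi
CYP2D6	PM	-1	0
CYP2D6	IM	0	1
CYP2D6	NM	1	2.25
CYP2D6	UM	2.25	99
CYP2C19	PM	-1	0
CYP2C19	IM	0	1.75
CYP2C19	NM	1.75	2.25
CYP2C19	UM	2.25	99
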