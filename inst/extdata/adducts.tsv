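# Electrospray adducts supported by the annotation workflow.
# Columns:
#   name        adduct label
#   polarity    positive | negative
#   charge      signed charge state of the ion
#   formula_add elemental formula added to the neutral species ("" = none)
#   formula_sub elemental formula removed from the neutral species ("" = none)
# m/z = (M + mass(formula_add) - mass(formula_sub) - charge * m_electron) / |charge|
# [M-CH3]- convention: loss of a methyl radical with one extra electron.
name	polarity	charge	formula_add	formula_sub
[M+H]+	positive	1	H
[M+Na]+	positive	1	Na
[M+NH4]+	positive	1	NH4
[M-H]-	negative	-1		H
[M+Cl]-	negative	-1	Cl
[M-CH3]-	negative	-1		CH3
[M+HCOO]-	negative	-1	CHO2
[M+AcO]-	negative	-1	C2H3O2
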