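# Class-diagnostic MS/MS fragmentation rules.
# Columns:
#   scope    class:<label> or category:<GL|GP|SP|ST> the rule applies to
#   polarity positive | negative
#   adduct   restrict to one adduct label ("" = any adduct of the polarity)
#   kind     diagnostic        fixed-composition fragment ion (formula = ion composition)
#            neutral_loss      fixed-composition neutral loss (formula = neutral lost)
#            chain_nl          per-acyl-chain neutral loss of the free fatty acid
#                              (plus NH3 for ammoniated precursors)
#            chain_carboxylate per-acyl-chain carboxylate anion RCOO-
#            n_type            sphingoid-base fragment [LCB+H-2H2O]+ of
#                              glycosphingolipids/ceramides (chain-parameterised)
#   formula  elemental composition for fixed-formula kinds
#   required 1 = required evidence for the class, 0 = supporting
#   configurable 1 = site marked for user adjustment (N''-type entries)
#   label    human-readable tag used in reports
scope	polarity	adduct	kind	formula	required	configurable	label
class:PC	positive		diagnostic	C5H15NO4P	1	0	phosphocholine head group 184.0733
class:LPC	positive		diagnostic	C5H15NO4P	1	0	phosphocholine head group 184.0733
class:SM	positive		diagnostic	C5H15NO4P	1	0	phosphocholine head group 184.0733
class:PC	positive	[M+Na]+	neutral_loss	C3H9N	0	0	trimethylamine loss 59.0735
class:PC	positive	[M+Na]+	neutral_loss	C5H14NO4P	0	0	phosphocholine loss 183.0660
class:PE	positive		neutral_loss	C2H8NO4P	1	0	phosphoethanolamine loss 141.0191
class:PS	positive		neutral_loss	C3H8NO6P	1	0	phosphoserine loss 185.0089
class:PI	positive		neutral_loss	C6H13O9P	1	0	inositol phosphate loss 260.0297
class:PG	positive		neutral_loss	C3H9O6P	1	0	glycerophosphate loss 172.0137
class:PA	positive		neutral_loss	H3O4P	1	0	phosphoric acid loss 97.9769
class:CE	positive		diagnostic	C27H45	1	0	cholestadienyl cation 369.3516
class:Chol	positive		diagnostic	C27H45	0	0	cholestadienyl cation 369.3516
class:TAG	positive		chain_nl		0	0	acyl chain fatty acid loss
class:DAG	positive		chain_nl		0	0	acyl chain fatty acid loss
class:MAG	positive		chain_nl		0	0	acyl chain fatty acid loss
class:Cer	positive		n_type		1	1	sphingoid base N''-type fragment
class:HexCer	positive		n_type		1	1	sphingoid base N''-type fragment
class:HexCer	positive		neutral_loss	C6H10O5	0	0	hexose loss 162.0528
class:Cer	positive		neutral_loss	H2O	0	0	water loss
category:GP	negative		chain_carboxylate		1	0	acyl chain carboxylate anion
category:SP	negative		chain_carboxylate		0	0	acyl chain carboxylate anion
category:GL	negative		chain_carboxylate		0	0	acyl chain carboxylate anion
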