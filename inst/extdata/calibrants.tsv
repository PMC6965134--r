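# ESI tuning-mix calibrant ions used for linear TIMS scan calibration.
# Columns: mz, ook0 (reduced mobility 1/K0, Vs/cm^2), polarity
mz	ook0	polarity
322.0481	0.7318	positive
622.0289	0.9848	positive
922.0097	1.1895	positive
1221.9906	1.3820	positive
666.01879	1.0371	negative
965.9996	1.2255	negative
1265.9809	1.3785	negative
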