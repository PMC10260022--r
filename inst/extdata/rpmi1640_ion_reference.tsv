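ion	mM
Na	138.52
K	5.33
Cl	108.78
Ca	0.42
Mg	0.41
phosphate	5.63
sulfate	0.41
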