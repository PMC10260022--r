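component	ion	mmol_per_mmol
arginine	Cl	1
lysine	Cl	1
histidine	Cl	1
ornithine	Cl	1
choline	Cl	1
cystine	Cl	2
lactate	Na	1
pyruvate	Na	1
glycerophosphocholine	phosphate	1
creatine-phosphate	phosphate	1
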