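name	target_uM	pool_id
alanine	400	1
arginine	2	2
asparagine	60	3
aspartate	25	4
cysteine	40	5
glutamate	90	6
glutamine	450	7
glycine	150	8
histidine	55	9
isoleucine	70	10
leucine	110	1
lysine	190	2
methionine	35	3
phenylalanine	65	4
proline	140	5
serine	200	6
threonine	160	7
tryptophan	45	8
tyrosine	60	9
valine	150	10
citrulline	67	1
ornithine	30	2
taurine	120	3
hypotaurine	8	4
creatine	85	5
creatinine	30	6
carnitine	25	7
acetylcarnitine	9	8
betaine	40	9
choline	18	10
sarcosine	3	1
cystathionine	2	2
beta-alanine	4	3
GABA	1.5	4
1-methylhistidine	6	5
3-methylhistidine	3	6
hydroxyproline	14	7
dimethylarginine	1.2	8
kynurenine	2.5	9
carnosine	5	10
anserine	2	1
ergothioneine	3	2
2-aminobutyrate	12	3
5-aminovalerate	1.5	4
N-acetylglycine	2	5
N-acetylalanine	4	6
N-acetylaspartate	3	7
glycylproline	1.8	8
homoserine	2.2	9
alpha-aminoadipate	2.8	10
lactate	9000	1
pyruvate	60	2
citrate	110	3
succinate	30	4
fumarate	8	5
malate	20	6
alpha-ketoglutarate	9	7
3-hydroxybutyrate	180	8
acetate	250	9
formate	40	10
propionate	6	1
butyrate	3	2
glycolate	12	3
glycerate	9	4
2-hydroxyglutarate	4	5
itaconate	1.2	6
urate	35	7
urea	6000	8
2-hydroxybutyrate	25	9
4-hydroxyphenyllactate	2.5	10
phenyllactate	3	1
indole-3-lactate	1.5	2
hippurate	4	3
quinolinate	1.1	4
alpha-glycerophosphate	15	5
glucose	4500	6
fructose	50	7
mannose	30	8
galactose	20	9
myo-inositol	90	10
sorbitol	10	1
glycerol	220	2
ribose	9	3
xylitol	3	4
arabitol	4	5
erythritol	6	6
glucosamine	8	7
N-acetylglucosamine	12	8
glucuronate	5	9
threitol	3	10
hypoxanthine	20	1
xanthine	6	2
inosine	8	3
uridine	10	4
cytidine	4	5
adenosine	1.2	6
guanosine	1.5	7
adenine	1.1	8
uracil	5	9
thymidine	2	10
allantoin	25	1
orotate	1.6	2
pseudouridine	4	3
nicotinamide	12	4
riboflavin	0.8	5
thiamine	1.2	6
pantothenate	4	7
pyridoxine	1.1	8
folate	0.9	9
biotin	0.6	10
4-aminobenzoate	0.7	1
nicotinate	2.5	2
pyridoxal	0.8	3
glycerophosphocholine	30	4
phosphocholine	6	5
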