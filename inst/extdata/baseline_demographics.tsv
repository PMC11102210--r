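group	n	variable	level	count
Healthy	30	sex	male	3
Healthy	30	sex	female	27
Healthy	30	race	white	27
Healthy	30	race	black	3
Healthy	30	race	asian	0
Healthy	30	smoker	no	29
B	53	sex	male	10
B	53	sex	female	43
B	53	race	white	47
B	53	race	black	5
B	53	race	asian	1
B	53	smoker	no	52
BF	50	sex	male	12
BF	50	sex	female	38
BF	50	race	white	43
BF	50	race	black	7
BF	50	race	asian	0
BF	50	smoker	no	50
BA	51	sex	male	6
BA	51	sex	female	45
BA	51	race	white	44
BA	51	race	black	7
BA	51	race	asian	0
BA	51	smoker	no	49
BZ	52	sex	male	15
BZ	52	sex	female	37
BZ	52	race	white	48
BZ	52	race	black	4
BZ	52	race	asian	0
BZ	52	smoker	no	52
BFZ	52	sex	male	15
BFZ	52	sex	female	37
BFZ	52	race	white	45
BFZ	52	race	black	7
BFZ	52	race	asian	0
BFZ	52	smoker	no	49
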