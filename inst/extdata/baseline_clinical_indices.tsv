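group	n	region	index	mean	sd
Healthy	30	whole_mouth	MGI	0.594	0.076
Healthy	30	whole_mouth	TPI	2.469	0.371
Healthy	30	whole_mouth	EBI	0.018	0.016
Healthy	30	whole_mouth	PPD	1.731	0.234
Healthy	30	interproximal	MGI	0.889	0.104
Healthy	30	interproximal	TPI	2.715	0.332
Healthy	30	interproximal	EBI	0.005	0.008
Healthy	30	interproximal	PPD	0.007	0.020
B	53	whole_mouth	MGI	2.560	0.305
B	53	whole_mouth	TPI	3.068	0.403
B	53	whole_mouth	EBI	0.308	0.187
B	53	whole_mouth	PPD	2.048	0.319
B	53	interproximal	MGI	2.738	0.269
B	53	interproximal	TPI	3.200	0.382
B	53	interproximal	EBI	0.305	0.191
B	53	interproximal	PPD	2.309	0.328
BF	50	whole_mouth	MGI	2.578	0.270
BF	50	whole_mouth	TPI	3.133	0.407
BF	50	whole_mouth	EBI	0.343	0.174
BF	50	whole_mouth	PPD	2.048	0.307
BF	50	interproximal	MGI	2.744	0.225
BF	50	interproximal	TPI	3.275	0.369
BF	50	interproximal	EBI	0.342	0.176
BF	50	interproximal	PPD	2.290	0.312
BA	51	whole_mouth	MGI	2.563	0.320
BA	51	whole_mouth	TPI	2.980	0.468
BA	51	whole_mouth	EBI	0.304	0.169
BA	51	whole_mouth	PPD	1.998	0.329
BA	51	interproximal	MGI	2.722	0.286
BA	51	interproximal	TPI	3.130	0.413
BA	51	interproximal	EBI	0.296	0.178
BA	51	interproximal	PPD	2.242	0.344
BZ	52	whole_mouth	MGI	2.653	0.288
BZ	52	whole_mouth	TPI	3.001	0.364
BZ	52	whole_mouth	EBI	0.366	0.195
BZ	52	whole_mouth	PPD	2.122	0.395
BZ	52	interproximal	MGI	2.796	0.226
BZ	52	interproximal	TPI	3.138	0.329
BZ	52	interproximal	EBI	0.367	0.206
BZ	52	interproximal	PPD	2.386	0.404
BFZ	52	whole_mouth	MGI	2.633	0.261
BFZ	52	whole_mouth	TPI	3.031	0.432
BFZ	52	whole_mouth	EBI	0.319	0.186
BFZ	52	whole_mouth	PPD	2.068	0.334
BFZ	52	interproximal	MGI	2.785	0.208
BFZ	52	interproximal	TPI	3.178	0.386
BFZ	52	interproximal	EBI	0.311	0.186
BFZ	52	interproximal	PPD	2.312	0.340
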