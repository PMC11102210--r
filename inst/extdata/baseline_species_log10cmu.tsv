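species	healthy_mean	healthy_sd	gingivitis_mean	gingivitis_sd	difference	p_printed
Abiotrophia defectiva	4.020	2.968	5.207	2.767	1.188	0.002
Actinomyces dentalis	6.064	1.912	6.735	1.429	0.671	0.015
Actinomyces naeslundii	6.654	0.752	7.041	0.687	0.388	0.004
Actinomyces oris	6.981	0.571	7.289	0.554	0.308	0.003
Actinomyces viscosus	7.129	0.532	7.383	0.562	0.254	0.009
Alloprevotella tannerae	2.146	2.745	3.371	2.933	1.225	0.025
Atopobium parvulum	3.662	2.707	4.556	2.605	0.894	0.034
Campylobacter curvus	0.629	1.635	1.802	2.425	1.174	0.011
Campylobacter gracilis	5.391	1.238	5.637	1.644	0.246	0.005
Capnocytophaga endodontalis	5.596	1.219	5.948	1.020	0.351	0.039
Capnocytophaga ochracea	5.893	1.358	6.231	1.441	0.337	0.008
Fusobacterium hwasookii	2.508	2.466	3.456	2.299	0.948	0.037
Fusobacterium nucleatum	4.815	1.538	5.324	1.322	0.509	0.013
Granulicatella adiacens	6.289	1.354	6.742	0.899	0.452	0.011
Lachnoanaerobaculum saburreum	4.674	2.309	5.726	1.678	1.052	0.003
Leptotrichia buccalis	3.646	2.365	4.997	2.126	1.351	<0.001
Leptotrichia goodfellowii	1.203	2.224	2.483	2.603	1.281	0.015
Leptotrichia hofstadii	4.694	2.272	5.566	1.779	0.872	0.008
Leptotrichia massiliensis	4.029	2.157	5.118	1.990	1.089	<0.001
Leptotrichia shahii	3.321	2.339	4.621	2.010	1.3	<0.001
Leptotrichia trevisanii	3.743	2.020	4.602	1.826	0.859	<0.001
Leptotrichia wadei	4.344	2.384	5.409	1.967	1.065	0.004
Prevotella melaninogenica	3.249	2.754	4.375	2.430	1.126	0.031
Prevotella oralis	0.195	1.070	1.156	2.226	0.961	0.02
Streptococcus gordonii	5.853	0.844	6.372	0.980	0.518	0.001
Streptococcus halitosis	5.393	0.663	5.669	0.940	0.277	0.008
Streptococcus intermedius	4.549	2.282	5.253	1.965	0.703	0.049
Streptococcus mitis	5.870	0.758	6.114	0.986	0.244	0.026
Streptococcus mutans	1.368	2.808	2.814	3.321	1.445	0.03
Streptococcus sanguinis	6.374	0.832	6.657	0.785	0.283	0.04
Streptococcus sinensis	3.999	1.889	4.689	1.367	0.691	0.008
Streptococcus symci	3.820	1.794	4.274	1.737	0.453	0.015
Veillonella dispar	6.922	0.571	7.110	1.068	0.188	0.007
Veillonella infantium	3.981	1.903	4.370	1.842	0.389	0.04
Veillonella parvula	6.930	0.580	7.158	0.938	0.228	0.007
Veillonella tobetsuensis	1.193	2.039	2.207	2.431	1.014	0.025
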