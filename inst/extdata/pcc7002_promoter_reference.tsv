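locus	product	rnaseq_mean	mean_norm_fluor	sd_norm_fluor	significant	rnaseq_class	rnaseq_slope	fluor_class	fluor_slope	correlation_r
A0047	Hypothetical protein	2.17e-04	1.322	0.116	TRUE	stationary_phase	9.68e-04	constitutive	-0.0192	0.0967
A0255	UDP-N-acetyl-D-mannosaminuronic acid transferase	5.09e-05	1.073	0.133	FALSE	stationary_phase	1.63e-05	constitutive	-0.0265	-0.722
A0304	Hypothetical protein	5.55e-05	1.038	0.158	FALSE	linear_phase	-1.77e-05	constitutive	-0.107	0.715
A0318	Hypothetical protein	8.72e-04	1.137	0.135	TRUE	constitutive	5.75e-06	constitutive	0.196	0.212
A0670	Hypothetical protein	2.16e-05	1.239	0.442	FALSE	constitutive	5.72e-07	constitutive	0.178	0.678
A0740	ATP synthase subunit I	1.04e-03	1.186	0.0919	TRUE	linear_phase	-2.73e-04	constitutive	3.83e-04	-0.628
A1173	Polyketide synthase	1.22e-03	1.087	0.0914	TRUE	constitutive	1.62e-05	constitutive	0.172	0.252
A1181	ATPase AAA	2.58e-03	1.074	0.0937	FALSE	stationary_phase	9.41e-04	constitutive	-0.0108	-0.0121
A1731	Hypothetical protein	6.03e-05	1.075	0.0967	FALSE	constitutive	-8.49e-07	constitutive	0.0640	0.181
A1798	Ribulose bisphosphate carboxylase, large subunit	4.77e-03	4.153	2.17	TRUE	linear_phase	-6.24e-04	stationary_phase	2.88	-0.335
A1929	Allophycocyanin subunit beta	1.29e-02	1.046	0.0866	FALSE	linear_phase	-2.75e-03	constitutive	-0.0547	0.800
A1930	Allophycocyanin subunit alpha	7.46e-03	2.338	0.197	TRUE	linear_phase	-1.51e-03	constitutive	-0.107	0.249
A1961	Photosystem I P700 chlorophyll-a apoprotein A1	1.95e-02	2.076	0.237	TRUE	constitutive	6.59e-04	stationary_phase	0.744	0.348
A1962	Photosystem I P700 chlorophyll-a apoprotein A2	2.61e-02	1.059	0.126	FALSE	stationary_phase	2.42e-03	constitutive	-0.0533	0.256
A2062	Elongation factor G	5.33e-03	1.038	0.00945	TRUE	constitutive	3.95e-06	constitutive	0.0392	-0.0315
A2127	Acetyl-CoA carboxylase biotin carboxylase subunit	3.62e-04	1.073	0.0576	TRUE	constitutive	1.64e-06	constitutive	0.0583	0.457
A2165	Hypothetical protein	9.95e-05	1.205	0.129	TRUE	stationary_phase	3.20e-05	constitutive	0.148	0.960
A2210	C-phycocyanin subunit alpha	2.91e-02	1.129	0.191	FALSE	linear_phase	-4.85e-03	constitutive	0.163	-0.907
A2520	Hypothetical protein	7.27e-05	31.88	4.61	TRUE	linear_phase	-2.78e-05	stationary_phase	35.4	-0.954
A2531	Hypothetical protein	1.24e-02	2.340	0.199	TRUE	constitutive	-7.74e-04	constitutive	0.105	-0.638
A2579	Hypothetical protein	6.80e-03	33.51	6.28	TRUE	linear_phase	-2.79e-03	stationary_phase	30.2	-0.968
A2595	Hypothetical protein	9.20e-04	1.061	0.107	FALSE	stationary_phase	3.90e-04	constitutive	-0.0697	-0.972
A2596	Hypothetical protein	2.77e-04	1.108	0.0762	TRUE	stationary_phase	9.99e-05	constitutive	-0.0649	-0.895
A2663	Bacterioferritin	2.87e-04	1.490	0.169	TRUE	linear_phase	-6.99e-05	constitutive	0.0140	-0.116
A2813	S-layer protein	2.47e-02	3.486	0.791	TRUE	stationary_phase	2.26e-03	constitutive	0.108	-0.213
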