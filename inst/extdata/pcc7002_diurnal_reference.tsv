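strain	signed_fold_change	sd	significant
A0047	1.01	0.38	FALSE
A0255	1.01	0.25	FALSE
A0304	1.29	0.089	FALSE
A0318	1.39	0.34	FALSE
A0670	1.31	0.20	FALSE
A0740	1.44	0.54	FALSE
A1173	1.41	0.34	FALSE
A1181	1.79	0.39	FALSE
A1731	1.85	0.79	TRUE
A1798	1.16	0.13	FALSE
A1929	-1.09	0.30	FALSE
A1930	1.11	0.017	FALSE
A1961	-1.33	0.30	FALSE
A1962	1.03	0.39	FALSE
A2062	1.46	0.23	FALSE
A2127	1.21	0.40	FALSE
A2165	1.45	0.015	TRUE
A2210	-1.34	0.44	FALSE
A2520	2.02	0.90	FALSE
A2531	1.35	0.031	FALSE
A2579	1.14	0.45	FALSE
A2595	1.45	0.42	FALSE
A2596	-1.05	0.10	FALSE
A2663	1.13	0.31	FALSE
A2813	2.28	0.73	FALSE
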