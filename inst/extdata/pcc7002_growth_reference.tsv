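strain	linear_growth_rate	sd_growth_rate	fv_fm	sd_fv_fm
WT	0.0334	0.0103	0.191	0.0712
dNS1	0.0371	0.0149	0.203	0.0422
dNS2	0.0346	0.00923	0.163	0.0428
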