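site	start	end	left_locus	right_locus
NS1	963217	964242	SYNPCC7002_A0932	SYNPCC7002_A0933
NS2	1247018	1248056	SYNPCC7002_A1202	SYNPCC7002_A1203
NS3	1864422	1865821	SYNPCC7002_A1778	SYNPCC7002_A1779
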