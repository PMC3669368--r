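snp_id	rs7074818	rs4240498	rs6537494	rs4298825	rs4488117	rs12245255
rs7074818	1.00	0.90	0.94	0.37	0.38	0.84
rs4240498	0.90	1.00	0.96	0.37	0.40	0.90
rs6537494	0.94	0.96	1.00	0.40	0.41	0.90
rs4298825	0.37	0.37	0.40	1.00	0.94	0.42
rs4488117	0.38	0.40	0.41	0.94	1.00	0.45
rs12245255	0.84	0.90	0.90	0.42	0.45	1.00
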