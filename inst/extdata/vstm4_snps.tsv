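snp_id	bp_downstream
rs7074818	11696
rs4240498	10038
rs6537494	9824
rs4298825	2915
rs4488117	312
rs12245255	0
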