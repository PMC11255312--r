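taxon_id	gene_id	sample_id	abundance
T1	K00001	S1	20
T1	K90001	S2	80
T2	K00002	S1	50
T3	GH1	S2	160
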