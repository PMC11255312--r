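sample_id	ec
S1	0.5
S2	9.8
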