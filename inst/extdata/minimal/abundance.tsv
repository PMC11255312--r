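taxon_id	S1	S2
T1	10	40
T2	25	5
T3	0	80
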