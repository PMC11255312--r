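taxon_id	domain	phylum	genus	genome_size_mb
T1	bacteria	Proteobacteria	Halomonas	3.2
T2	bacteria	Chloroflexi	Bacillus	4.8
T3	archaea	Euryarchaeota	NA	NA
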