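taxon	copy_number
Escherichia	7
Bacillus	10
Pseudomonas	4
Nitrospira	1
Dechloromonas	3
Rhodocyclaceae	3
Flavobacterium	5
Streptomyces	6
Planctomycetes	1
Acidobacteria	1
Chloroflexi	2
Zoogloea	3
Thauera	4
Acinetobacter	6
Nitrosomonas	1
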