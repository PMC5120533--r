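stage	quantity	count
spikelet	deg_parents	12550
spikelet	genes_analyzed_de	23038
spikelet	additive	10093
spikelet	non_additive	3577
spikelet	inheritance_total	13670
spikelet	ng5_dominant	1981
spikelet	ase_snps	44675
spikelet	ase_reads_covering_snps	3113870
spikelet	ase_genes_tagged	12637
spikelet	ase_biased_genes	7126
spikelet	ase_maternal_biased	2514
spikelet	ase_paternal_biased	4612
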