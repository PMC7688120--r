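snp_id	chrom	pos	hr_allele	control_allele
rs29503987	chr17	18001459	C	A
rs33375308	chr17	18210739	T	C
rs33447983	chr17	19403011	G	T
rs6224641	chr17	19424358	A	G
rs33649277	chr17	19616228	G	A
rs29522462	chr17	20573305	A	C
rs33120398	chr17	20587484	C	T
rs33463529	chr17	20779567	G	A
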