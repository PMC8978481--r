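token	type_curie	database
hgnc	edam:data_2298	HGNC
ensembl	edam:data_1033	Ensembl
ncbigene	edam:data_1027	Entrez Gene
uniprot	edam:data_2291	UniProt
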