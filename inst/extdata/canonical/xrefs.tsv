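source_db	source_id	target_db	target_id
cas	103-90-2	chebi	46195
cas	103-90-2	chemspider	1906
cas	103-90-2	wikidata	Q57055
cas	103-90-2	chembl.compound	CHEMBL112
cas	103-90-2	pubchem.compound	1983
cas	103-90-2	drugbank	DB00316
cas	103-90-2	kegg.compound	C06804
cas	103-90-2	lipidmaps	LMFA01010042
cas	103-90-2	hmdb	HMDB0001859
cas	25812-30-0	chebi	5296
cas	25812-30-0	chemspider	3368
cas	25812-30-0	wikidata	Q412394
cas	25812-30-0	pubchem.compound	3463
hgnc	UROD	ncbigene	7389
hgnc	UROD	uniprot	P06132
hgnc	UROD	ensembl	ENSG00000126088
hgnc	HDAC9	ncbigene	9734
hgnc	HDAC9	uniprot	Q9UKV0
hgnc	HDAC9	ensembl	ENSG00000048052
hgnc	PRDX2	ncbigene	7001
hgnc	PRDX2	uniprot	P32119
hgnc	PRDX2	ensembl	ENSG00000167815
hgnc	ALAD	ncbigene	210
hgnc	ALAD	uniprot	P13716
hgnc	ALAD	ensembl	ENSG00000148218
hgnc	GSR	ncbigene	2936
hgnc	GSR	uniprot	P00390
hgnc	GSR	ensembl	ENSG00000104687
hgnc	TNF	ncbigene	7124
hgnc	TNF	uniprot	P01375
hgnc	TNF	ensembl	ENSG00000232810
hgnc	IL6	ncbigene	3569
hgnc	IL6	uniprot	P05231
hgnc	IL6	ensembl	ENSG00000136244
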