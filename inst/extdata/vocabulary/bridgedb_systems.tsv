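system_code	system_name	token
Ca	CAS	cas
Ce	ChEBI	chebi
Cs	Chemspider	chemspider
Cl	ChEMBL compound	chembl.compound
Cpc	PubChem-compound	pubchem.compound
Dr	DrugBank	drugbank
Ck	KEGG Compound	kegg.compound
Lm	LIPID MAPS	lipidmaps
Ch	HMDB	hmdb
Ik	InChIKey	inchikey
H	HGNC	hgnc
L	Entrez Gene	ncbigene
S	Uniprot-TrEMBL	uniprot
En	Ensembl	ensembl
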