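token	type_curie	database
cas	cheminf:000446	CAS
chebi	cheminf:000407	ChEBI
chemspider	cheminf:000405	ChemSpider
chembl.compound	cheminf:000412	ChEMBL compound
comptox	cheminf:000568	CompTox
drugbank	cheminf:000406	Drugbank
hmdb	cheminf:000408	HMDB
inchikey	cheminf:000059	InChIKey
kegg.compound	cheminf:000409	KEGG compound
lipidmaps	cheminf:000564	Lipid maps
pubchem.compound	cheminf:000140	PubChem compound
wikidata	cheminf:000567	Wikidata
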