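prefix	base_iri	category	source
dc	http://purl.org/dc/elements/1.1/	metadata	core
dcterms	http://purl.org/dc/terms/	metadata	core
rdfs	http://www.w3.org/2000/01/rdf-schema#	metadata	core
foaf	http://xmlns.com/foaf/0.1/	metadata	core
aopo	http://aopkb.org/aop_ontology#	domain	core
pato	http://purl.obolibrary.org/obo/PATO_	domain	core
cheminf	http://semanticscience.org/resource/CHEMINF_	domain	core
nci	http://ncicb.nci.nih.gov/xml/owl/EVS/Thesaurus.owl#	domain	core
mmo	http://purl.obolibrary.org/obo/MMO_	domain	core
skos	http://www.w3.org/2004/02/skos/core#	metadata	core
ncbitaxon	http://purl.bioontology.org/ontology/NCBITAXON/	domain	core
go	http://purl.obolibrary.org/obo/GO_	domain	core
edam	http://edamontology.org/	domain	core
pav	http://purl.org/pav/	metadata	core
void	http://rdfs.org/ns/void#	metadata	core
dcat	http://www.w3.org/ns/dcat#	metadata	core
rdf	http://www.w3.org/1999/02/22-rdf-syntax-ns#	metadata	syntax
xsd	http://www.w3.org/2001/XMLSchema#	metadata	syntax
cl	http://purl.obolibrary.org/obo/CL_	domain	annex
uberon	http://purl.obolibrary.org/obo/UBERON_	domain	annex
mi	http://purl.obolibrary.org/obo/MI_	domain	annex
mp	http://purl.obolibrary.org/obo/MP_	domain	annex
mesh	http://purl.bioontology.org/ontology/MESH/	domain	annex
hp	http://purl.obolibrary.org/obo/HP_	domain	annex
pco	http://purl.obolibrary.org/obo/PCO_	domain	annex
nbo	http://purl.obolibrary.org/obo/NBO_	domain	annex
vt	http://purl.obolibrary.org/obo/VT_	domain	annex
pr	http://purl.obolibrary.org/obo/PR_	domain	annex
fma	http://purl.org/sig/ont/fma/fma	domain	annex
aop	https://identifiers.org/aop/	identifier	identifier
aop.events	https://identifiers.org/aop.events/	identifier	identifier
aop.relationships	https://identifiers.org/aop.relationships/	identifier	identifier
aop.stressor	https://identifiers.org/aop.stressor/	identifier	identifier
cas	https://identifiers.org/cas/	identifier	identifier
inchikey	https://identifiers.org/inchikey/	identifier	identifier
comptox	https://identifiers.org/comptox/	identifier	identifier
chebi	https://identifiers.org/chebi/	identifier	identifier
chemspider	https://identifiers.org/chemspider/	identifier	identifier
wikidata	https://identifiers.org/wikidata/	identifier	identifier
chembl.compound	https://identifiers.org/chembl.compound/	identifier	identifier
pubchem.compound	https://identifiers.org/pubchem.compound/	identifier	identifier
drugbank	https://identifiers.org/drugbank/	identifier	identifier
kegg.compound	https://identifiers.org/kegg.compound/	identifier	identifier
lipidmaps	https://identifiers.org/lipidmaps/	identifier	identifier
hmdb	https://identifiers.org/hmdb/	identifier	identifier
hgnc	https://identifiers.org/hgnc/	identifier	identifier
ncbigene	https://identifiers.org/ncbigene/	identifier	identifier
uniprot	https://identifiers.org/uniprot/	identifier	identifier
ensembl	https://identifiers.org/ensembl/	identifier	identifier
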