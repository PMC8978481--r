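entity_kind	ord	predicate	object_kind	cardinality	field	graph
aop	1	rdf:type	iri_ref	one	type	main
aop	2	dc:identifier	iri_ref	one	id	main
aop	3	rdfs:label	literal	one	label	main
aop	4	dc:title	literal	one	title	main
aop	5	dcterms:alternative	literal	optional	alternative_title	main
aop	6	dc:creator	literal	many	creators	main
aop	7	dcterms:abstract	literal	optional	abstract	main
aop	8	nci:C54571	iri_ref	many	stressor_ids	main
aop	9	aopo:has_key_event	iri_ref	many	ke_ids	main
aop	10	aopo:has_molecular_initiating_event	iri_ref	many	mie_ids	main
aop	11	aopo:has_adverse_outcome	iri_ref	many	ao_ids	main
aop	12	aopo:has_key_event_relationship	iri_ref	many	ker_ids	main
aop	13	dc:description	literal	optional	description	main
aop	14	pato:0000047	literal	optional	sex_applicability	main
aop	15	aopo:LifeStageContext	literal	optional	life_stage	main
aop	16	aopo:AopContext	literal	optional	applicability_text	main
aop	17	edam:operation_3799	literal	optional	quantitative_considerations	main
aop	18	aopo:has_evidence	literal	optional	weight_of_evidence	main
aop	19	nci:C25725	literal	optional	potential_applications	main
aop	20	nci:C25217	literal	optional	overall_assessment	main
aop	21	nci:C48192	literal	optional	ke_essentiality	main
aop	22	dc:accessRights	literal	optional	status	main
aop	23	foaf:page	url	one	page	main
aop	24	dcterms:created	typed_literal	optional	created	main
aop	25	dcterms:modified	typed_literal	optional	modified	main
aop	26	dc:source	literal	one	source	main
ke	1	rdf:type	iri_ref	one	type	main
ke	2	dc:identifier	iri_ref	one	id	main
ke	3	rdfs:label	literal	one	label	main
ke	4	dc:title	literal	one	title	main
ke	5	dcterms:alternative	literal	optional	alternative_title	main
ke	6	nci:C25664	literal	optional	bio_level	main
ke	7	dc:description	literal	optional	description	main
ke	8	edam:data_1025	iri_ref	many	gene_ids	genes
ke	9	mmo:0000000	literal	optional	measurement_method	main
ke	10	nci:C54571	iri_ref	many	stressor_ids	main
ke	11	aopo:CellTypeContext	iri_ref	optional	cell_term	main
ke	12	aopo:OrganContext	iri_ref	optional	organ_term	main
ke	13	go:0008150	iri_ref	many	process_terms	main
ke	14	pato:0001241	iri_ref	many	object_terms	main
ke	15	pato:0000001	iri_or_literal	many	action_terms	main
ke	16	ncbitaxon:131567	iri_or_literal	many	taxa	main
ke	17	pato:0000047	literal	optional	sex_applicability	main
ke	18	aopo:LifeStageContext	literal	optional	life_stage	main
ke	19	foaf:page	url	one	page	main
ke	20	dcterms:isPartOf	iri_ref	many	aop_ids	main
ke	21	dc:source	literal	one	source	main
ker	1	rdf:type	iri_ref	one	type	main
ker	2	dc:identifier	iri_ref	one	id	main
ker	3	rdfs:label	literal	one	label	main
ker	4	aopo:has_upstream_key_event	iri_ref	one	upstream_ke	main
ker	5	aopo:has_downstream_key_event	iri_ref	one	downstream_ke	main
ker	6	dc:description	literal	optional	description	main
ker	7	nci:C80263	literal	optional	biological_plausibility	main
ker	8	edam:data_2042	literal	optional	empirical_support	main
ker	9	nci:C71478	literal	optional	uncertainties	main
ker	10	edam:data_1025	iri_ref	many	gene_ids	genes
ker	11	ncbitaxon:131567	iri_or_literal	many	taxa	main
ker	12	pato:0000047	literal	optional	sex_applicability	main
ker	13	aopo:LifeStageContext	literal	optional	life_stage	main
ker	14	foaf:page	url	one	page	main
ker	15	dcterms:created	typed_literal	optional	created	main
ker	16	dcterms:modified	typed_literal	optional	modified	main
ker	17	dcterms:isPartOf	iri_ref	many	aop_ids	main
stressor	1	rdf:type	iri_ref	one	type	main
stressor	2	dc:identifier	iri_ref	one	id	main
stressor	3	rdfs:label	literal	one	label	main
stressor	4	dc:title	literal	one	title	main
stressor	5	dc:description	literal	optional	description	main
stressor	6	aopo:has_chemical_entity	iri_ref	many	chemical_cas	main
stressor	7	foaf:page	url	one	page	main
stressor	8	dcterms:created	typed_literal	optional	created	main
stressor	9	dcterms:modified	typed_literal	optional	modified	main
stressor	10	dcterms:isPartOf	iri_ref	many	parents	main
chemical	1	rdf:type	iri_ref	one	type	main
chemical	2	dc:identifier	iri_ref	one	id	main
chemical	3	cheminf:000446	literal	one	cas	main
chemical	4	dc:title	literal	one	name	main
chemical	5	dcterms:alternative	literal	many	synonyms	main
chemical	6	cheminf:000059	iri_ref	optional	inchikey	main
chemical	7	cheminf:000568	iri_ref	optional	comptox	main
chemical	8	skos:exactMatch	iri_ref	many	xrefs	main
chemical	9	dcterms:isPartOf	iri_ref	many	stressor_ids	main
term	1	rdf:type	iri_ref	one	type	main
term	2	dc:identifier	iri_ref	one	id	main
term	3	dc:title	literal	optional	label	main
term	4	skos:exactMatch	iri_ref	many	xrefs	main
term	5	dc:source	literal	one	source	main
gene	1	rdf:type	iri_ref	one	type	genes
gene	2	rdfs:label	literal	one	label	genes
gene	3	skos:exactMatch	iri_ref	many	xrefs	genes
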