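hgnc_id	symbol	name	alias_symbol	alias_name
HGNC:12591	UROD	uroporphyrinogen decarboxylase		
HGNC:395	ALAD	aminolevulinate dehydratase	ALADH	porphobilinogen synthase
HGNC:14065	HDAC9	histone deacetylase 9	HDAC7B|KIAA0744	histone deacetylase 7B
HGNC:9353	PRDX2	peroxiredoxin 2	NKEFB|TSA	thiol-specific antioxidant protein
HGNC:11998	TP53	tumor protein p53	p53	tumor suppressor p53
HGNC:1100	BRCA1	BRCA1 DNA repair associated	RNF53	breast cancer 1
HGNC:3236	EGFR	epidermal growth factor receptor	ERBB1	avian erythroblastic leukemia viral oncogene homolog
HGNC:11892	TNF	tumor necrosis factor	TNFA|TNFSF2	tumor necrosis factor alpha
HGNC:6018	IL6	interleukin 6	IFNB2	interferon beta 2
HGNC:5	A1BG	alpha-1-B glycoprotein		
HGNC:620	APP	amyloid beta precursor protein	AD1	alzheimer disease amyloid protein
HGNC:11179	SOD1	superoxide dismutase 1	ALS1	amyotrophic lateral sclerosis 1
HGNC:2674	CYP1A1	cytochrome P450 family 1 subfamily A member 1	AHH	aryl hydrocarbon hydroxylase
HGNC:2637	CYP2E1	cytochrome P450 family 2 subfamily E member 1	CPE1	
HGNC:4931	AHR	aryl hydrocarbon receptor	bHLHe76	dioxin receptor
HGNC:11110	SLC6A4	solute carrier family 6 member 4	5-HTT|SERT	serotonin transporter
HGNC:7645	NFE2L2	NFE2 like bZIP transcription factor 2	NRF2	nuclear factor erythroid 2 related factor 2
HGNC:3535	ESR1	estrogen receptor 1	ER-alpha	estrogen receptor alpha
HGNC:644	AR	androgen receptor	DHTR	dihydrotestosterone receptor
HGNC:11850	TSHR	thyroid stimulating hormone receptor	LGR3	
HGNC:1097	BRAF	B-Raf proto-oncogene, serine/threonine kinase	BRAF1	
HGNC:6407	KRAS	KRAS proto-oncogene, GTPase	KRAS2	kirsten rat sarcoma viral oncogene homolog
HGNC:7989	MYC	MYC proto-oncogene, bHLH transcription factor	c-Myc	avian myelocytomatosis viral oncogene homolog
HGNC:1771	CDK4	cyclin dependent kinase 4	PSK-J3	
HGNC:990	BCL2	BCL2 apoptosis regulator	PPP1R50	B-cell lymphoma 2
HGNC:1504	CASP3	caspase 3	CPP32	apopain
HGNC:1509	CASP8	caspase 8	FLICE|MACH	
HGNC:6871	MAPK1	mitogen-activated protein kinase 1	ERK2|p42-MAPK	extracellular signal regulated kinase 2
HGNC:6840	MAP2K1	mitogen-activated protein kinase kinase 1	MEK1	
HGNC:391	AKT1	AKT serine/threonine kinase 1	PKB	protein kinase B
HGNC:8975	PIK3CA	phosphatidylinositol-4,5-bisphosphate 3-kinase catalytic subunit alpha	p110-alpha	
HGNC:11389	STAT3	signal transducer and activator of transcription 3	APRF	acute phase response factor
HGNC:6204	JUN	Jun proto-oncogene, AP-1 transcription factor subunit	AP-1|c-Jun	
HGNC:3796	FOS	Fos proto-oncogene, AP-1 transcription factor subunit	c-Fos	
HGNC:7562	MT1A	metallothionein 1A	MT1	metallothionein 1
HGNC:4556	GPX1	glutathione peroxidase 1	GSHPX1	
HGNC:2352	CAT	catalase		
HGNC:4632	GSR	glutathione-disulfide reductase	GR	glutathione reductase
HGNC:6389	KEAP1	kelch like ECH associated protein 1	INrf2	
HGNC:9588	PTGS2	prostaglandin-endoperoxide synthase 2	COX2|COX-2	cyclooxygenase 2
HGNC:7794	NFKB1	nuclear factor kappa B subunit 1	KBF1	
HGNC:6121	IL1B	interleukin 1 beta	IL-1B	interleukin 1 beta precursor
HGNC:6023	IL8	interleukin 8	CXCL8	neutrophil chemotactic factor
HGNC:11364	SREBF1	sterol regulatory element binding transcription factor 1	SREBP1	
HGNC:9236	PPARA	peroxisome proliferator activated receptor alpha	NR1C1	
HGNC:9237	PPARD	peroxisome proliferator activated receptor delta	NR1C2	
HGNC:9238	PPARG	peroxisome proliferator activated receptor gamma	NR1C3	
HGNC:11848	TSHB	thyroid stimulating hormone subunit beta		thyrotropin beta chain
HGNC:3061	DIO1	iodothyronine deiodinase 1	TXDI1	type 1 deiodinase
HGNC:1046	BDNF	brain derived neurotrophic factor		brain-derived neurotrophic factor
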