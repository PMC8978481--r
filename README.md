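# aopwikirdf

Convert AOP-Wiki-style XML dumps of **adverse outcome pathways (AOPs)** into
semantic-web RDF.

## The problem

The AOP-Wiki is the central repository for adverse outcome pathways: chains
of biological **key events (KEs)** that lead from a **molecular initiating
event (MIE)** — typically the perturbation of a protein by a chemical
stressor — through **key event relationships (KERs)** to an **adverse
outcome (AO)** used in chemical risk assessment. Its quarterly XML dumps
are, however, mostly free text and hard to query computationally, and they
carry few links to the chemical and gene databases where most of the
underlying biology lives.

`aopwikirdf` is a conversion tool for toxicologists, risk assessors and
bioinformaticians who want that content as a queryable knowledge graph. It

1. **parses** an AOP-Wiki-style XML dump into a typed knowledge model
   (AOPs, KEs, KERs, stressors, chemicals, and the ontology term
   annotations of KE components, cells, organs and taxa), driven by a
   configurable element-name dialect;
2. **enriches** it: KE/KER free text is scanned against an HGNC gene
   dictionary (boundary-aware exact matching over approved symbols, names
   and aliases), PRotein Ontology biological objects are mapped to
   UniProt/HGNC/NCBI Gene via a promapping-style table, and chemical CAS
   numbers / HGNC ids are expanded to nine chemical and three gene
   databases through a pluggable cross-reference backend (offline static
   table, or a BridgeDb-compatible HTTP service);
3. **emits** three deterministic Turtle files — the main knowledge graph
   (`AOP-Wiki.ttl`), the text-mapped gene graph (`AOP-Wiki-genes.ttl`) and
   VoID dataset metadata (`AOP-Wiki-void.ttl`) — in which every statement
   follows a declarative predicate schema. Entities resolve through
   identifiers.org compact-identifier IRIs (`aop:38` →
   `https://identifiers.org/aop/38`); a subject such as an AOP carries up
   to 26 distinct predicates drawn from Dublin Core, the AOP Ontology,
   NCI Thesaurus, PATO, EDAM, FOAF and friends; chemical identifier nodes
   are typed with CHEMINF classes (12 database types) and gene identifier
   nodes with EDAM classes (4 database types).

Validation (Turtle syntax, XSD datatypes, dangling internal links), graph
statistics (triple/subject/predicate/object totals, subjects per type,
link-outs per database, ontology-namespace usage), a SPARQL query catalog
(including a federated WikiPathways template), and a seeded
synthetic-fixture generator round out the toolkit, so the whole pipeline is
testable entirely offline.

## Worked example

The package ships a small canonical fixture bundle whose entities mirror
well-known AOP-Wiki records (AOP 38 "Protein Alkylation leading to Liver
Fibrosis", KE 1502 "Histone deacetylase inhibition", KER 865 with its UROD
mention, stressor 208 "Gemfibrozil", acetaminophen with full
cross-references):

```r
library(aopwikirdf)
fx <- canonical_fixture()
model <- parse_aopwiki_xml(fx[["xml"]])
model
#> AOP-Wiki knowledge model (snapshot 2021-01-01)
#> aops: 3
#> key events: 8
#> key event relationships: 3
#> stressors: 3
#> chemicals: 2
#> taxonomy terms: 3
#> cell terms: 2
#> organ terms: 2
#> ke component terms: 14
#> skipped entities: 0
#> dangling references: 0

conv <- convert_model(model,
  dict    = build_symbol_dictionary(fx[["hgnc"]]),
  pr_table = read_pr_mapping(fx[["pr"]]),
  backend = static_backend(fx[["xrefs"]]))
write_rdf_files(conv, "out")
```

The main graph now contains, for example (exactly as serialized):

```ttl
aop:38
    a aopo:AdverseOutcomePathway ;
    dc:identifier aop:38 ;
    rdfs:label "AOP 38" ;
    dc:title "Protein Alkylation leading to Liver Fibrosis" ;
    ...
    nci:C54571 aop.stressor:9 ;
    dcterms:created "2016-11-29T18:41:16"^^xsd:dateTime ;
```

and the gene graph links KER 865 to the UROD gene it mentions, with typed
cross-references:

```ttl
hgnc:UROD
    a edam:data_2298 ;
    rdfs:label "UROD" ;
    skos:exactMatch ensembl:ENSG00000126088, ncbigene:7389, uniprot:P06132 .
```

Statistics over the two data graphs:

```r
compute_stats(list(conv$main, conv$genes))
#> Graph statistics
#>   triples: 424  subjects: 83  predicates: 46  objects: 226
#>   subjects per type:
#>     aopo:AdverseOutcomePathway: 3
#>     aopo:KeyEvent: 8
#>     aopo:KeyEventRelationship: 3
#>     ...
#>   link-outs per database:
#>     chebi: 2
#>     ensembl: 7
#>     ncbigene: 9
#>     uniprot: 9
#>     ...
```

`triples: 424` is the deduplicated statement count; the per-type lines say,
e.g., that all 8 key events were typed, and the link-out lines count
`skos:exactMatch` statements by the database-type annotation of their
target (9 UniProt link-outs = 7 from text-mapped genes + 2 from PRotein
Ontology objects).

A command-line interface wraps the same workflow:

```sh
exec/aopwikirdf convert --xml dump.xml --hgnc hgnc.tsv --pr promapping.tsv \
    --xrefs xrefs.tsv --out-dir out
exec/aopwikirdf validate out/*.ttl
exec/aopwikirdf stats out/*.ttl --json stats.json
exec/aopwikirdf fixture --dir fixtures --seed 42
```

Exit codes: 0 success, 1 validation failure, 2 usage/configuration error.

## Scope notes

The real quarterly dump's element dialect is not standardized;
`aopwiki_dialect()` documents the fixture dialect this package reads and
accepts a YAML override file to adapt real dumps without code changes.
Hosting a SPARQL endpoint and executing the bundled federated query
template against remote services are out of scope.
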