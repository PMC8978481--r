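# name: federated_wikipathways
# category: federated
# network: required
# For every AOP-Wiki chemical with a ChEBI mapping, find the human molecular
# pathways it participates in at the WikiPathways SPARQL endpoint. Template
# only: execution requires network access to the remote endpoint.
PREFIX aopo: <http://aopkb.org/aop_ontology#>
PREFIX cheminf: <http://semanticscience.org/resource/CHEMINF_>
PREFIX skos: <http://www.w3.org/2004/02/skos/core#>
PREFIX dc: <http://purl.org/dc/elements/1.1/>
PREFIX dcterms: <http://purl.org/dc/terms/>
PREFIX wp: <http://vocabularies.wikipathways.org/wp#>
SELECT DISTINCT ?chemical ?name ?chebi ?stressor ?aop ?pathway ?pathwayTitle
WHERE {
  ?chemical a cheminf:000000 ;
            dc:title ?name ;
            skos:exactMatch ?chebi ;
            dcterms:isPartOf ?stressor .
  ?aop a aopo:AdverseOutcomePathway .
  ?chebi a cheminf:000407 .
  SERVICE <https://sparql.wikipathways.org/sparql> {
    ?wpChemical wp:bdbChEBI ?chebi ;
                dcterms:isPartOf ?pathway .
    ?pathway a wp:Pathway ;
             dc:title ?pathwayTitle ;
             wp:organismName "Homo sapiens" .
  }
}
ORDER BY ?chemical ?pathway
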