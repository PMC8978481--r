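# name: aop_components
# category: browsing
# Every AOP with its key events, molecular initiating events and adverse
# outcomes.
PREFIX aopo: <http://aopkb.org/aop_ontology#>
PREFIX dc: <http://purl.org/dc/elements/1.1/>
SELECT ?aop ?title ?ke ?mie ?ao
WHERE {
  ?aop a aopo:AdverseOutcomePathway ;
       dc:title ?title ;
       aopo:has_key_event ?ke .
  OPTIONAL { ?aop aopo:has_molecular_initiating_event ?mie }
  OPTIONAL { ?aop aopo:has_adverse_outcome ?ao }
}
ORDER BY ?aop ?ke
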