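# name: ke_measurement_methods
# category: browsing
# Measurement methods of all key events that are part of an AOP of interest
# (the adverse-outcome browsing pattern): bind ?aop upstream or remove the
# filter to list everything.
PREFIX aopo: <http://aopkb.org/aop_ontology#>
PREFIX dc: <http://purl.org/dc/elements/1.1/>
PREFIX mmo: <http://purl.obolibrary.org/obo/MMO_>
SELECT ?aop ?ke ?title ?method
WHERE {
  ?aop a aopo:AdverseOutcomePathway ;
       aopo:has_key_event ?ke .
  ?ke dc:title ?title ;
      mmo:0000000 ?method .
}
ORDER BY ?aop ?ke
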