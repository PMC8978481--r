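# name: chemical_linkouts
# category: browsing
# Chemicals with their names and every mapped external identifier.
PREFIX cheminf: <http://semanticscience.org/resource/CHEMINF_>
PREFIX skos: <http://www.w3.org/2004/02/skos/core#>
PREFIX dc: <http://purl.org/dc/elements/1.1/>
SELECT ?chemical ?name ?mapped
WHERE {
  ?chemical a cheminf:000000 ;
            dc:title ?name .
  OPTIONAL { ?chemical skos:exactMatch ?mapped }
}
ORDER BY ?chemical ?mapped
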