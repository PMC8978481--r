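# name: linkouts_by_database
# category: statistics
# Link-outs (skos:exactMatch statements) partitioned by the type annotation
# of the target identifier node.
PREFIX skos: <http://www.w3.org/2004/02/skos/core#>
SELECT ?dbtype (COUNT(*) AS ?n)
WHERE {
  ?s skos:exactMatch ?target .
  ?target a ?dbtype .
}
GROUP BY ?dbtype
ORDER BY ?dbtype
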