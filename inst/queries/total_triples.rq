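# name: total_triples
# category: statistics
# Total number of unique triples in the graph.
SELECT (COUNT(*) AS ?n)
WHERE { ?s ?p ?o }
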