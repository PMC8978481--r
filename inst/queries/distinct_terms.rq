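# name: distinct_terms
# category: statistics
# Unique subject, predicate and object counts.
SELECT (COUNT(DISTINCT ?s) AS ?subjects)
       (COUNT(DISTINCT ?p) AS ?predicates)
       (COUNT(DISTINCT ?o) AS ?objects)
WHERE { ?s ?p ?o }
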