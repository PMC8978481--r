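# name: gene_mentions
# category: browsing
# Key events / key event relationships with their text-mapped gene
# identifiers (run against the gene graph).
PREFIX edam: <http://edamontology.org/>
SELECT ?entity ?gene
WHERE { ?entity edam:data_1025 ?gene }
ORDER BY ?entity ?gene
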