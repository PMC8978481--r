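PR:000008478	uniprot:Q9UKV0	exact
PR:000008478	hgnc:HDAC9	exact
PR:000008478	ncbigene:9734	exact
PR:000016890	uniprot:P06132	exact
PR:000016890	hgnc:UROD	exact
PR:000016890	ncbigene:7389	exact
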