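kind	type_curie
cell	aopo:CellTypeContext
organ	aopo:OrganContext
taxonomy	ncbitaxon:131567
process	go:0008150
object	pato:0001241
action	pato:0000001
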