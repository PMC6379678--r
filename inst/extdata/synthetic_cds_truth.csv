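"gene_id","has_ramp","planted_length_codons"
"gene0001",TRUE,30
"gene0002",TRUE,33
"gene0003",FALSE,NA
"gene0004",TRUE,36
"gene0005",FALSE,NA
"gene0006",FALSE,NA
"gene0007",FALSE,NA
"gene0008",TRUE,31
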