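TTT,TTC,TTA,TTG,TCT,TCC,TCA,TCG,TAT,TAC,TGT,TGC,TGG,CTT,CTC,CTA,CTG,CCT,CCC,CCA,CCG,CAT,CAC,CAA,CAG,CGT,CGC,CGA,CGG,ATT,ATC,ATA,ATG,ACT,ACC,ACA,ACG,AAT,AAC,AAA,AAG,AGT,AGC,AGA,AGG,GTT,GTC,GTA,GTG,GCT,GCC,GCA,GCG,GAT,GAC,GAA,GAG,GGT,GGC,GGA,GGG
0.749,1,0.651,1,0.255,0.9536,1,0.7154,1,0.1678,1,0.8862,1,0.4545,0.856,0.5728,0.8016,1,0.4142,0.7947,0.9452,0.3759,1,0.5571,1,0.4757,0.07158,0.4717,1,0.6025,0.8199,1,1,0.2714,1,0.8194,0.9623,0.2068,1,0.531,1,0.7016,0.8378,0.6567,0.6314,1,0.09022,0.6293,0.9323,0.8156,0.5802,1,0.537,1,0.4146,0.4123,1,0.5917,0.7402,0.4759,1
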