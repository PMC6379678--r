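codon,value
TTT,0.749
TTC,1
TTA,0.651
TTG,1
TCT,0.255
TCC,0.9536
TCA,1
TCG,0.7154
TAT,1
TAC,0.1678
TGT,1
TGC,0.8862
TGG,1
CTT,0.4545
CTC,0.856
CTA,0.5728
CTG,0.8016
CCT,1
CCC,0.4142
CCA,0.7947
CCG,0.9452
CAT,0.3759
CAC,1
CAA,0.5571
CAG,1
CGT,0.4757
CGC,0.07158
CGA,0.4717
CGG,1
ATT,0.6025
ATC,0.8199
ATA,1
ATG,1
ACT,0.2714
ACC,1
ACA,0.8194
ACG,0.9623
AAT,0.2068
AAC,1
AAA,0.531
AAG,1
AGT,0.7016
AGC,0.8378
AGA,0.6567
AGG,0.6314
GTT,1
GTC,0.09022
GTA,0.6293
GTG,0.9323
GCT,0.8156
GCC,0.5802
GCA,1
GCG,0.537
GAT,1
GAC,0.4146
GAA,0.4123
GAG,1
GGT,0.5917
GGC,0.7402
GGA,0.4759
GGG,1
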