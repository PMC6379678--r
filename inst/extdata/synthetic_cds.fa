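>gene0001
ATGGACTACAAACTTTCTCATCATAATCGTGACAATCGCACTGAACATCATACTACTGACCATCATTACAATGACACTGT
CGAATCTCCCCTTTCATGCGAGGCTCAGACGCAGGGCATCTCAGCAGGCATGTCAGCCGAGTCAATAAGCCTGTTCGGGC
ACATTCTGGCTTTTGCATCAATCGGCTCAGCAGCCTGGCCGGTACTAGCAATGATGATCCAGGCCAACCTAATTAACACG
GGCAGAGGGCGGAGTGCTCCGTGTGCCATCCAAACCGGTAAGGAGAGCGCCAACAGGTGCTTTGGTACCCCTAACATAGA
GCTCGCCATAACGATTGCAAGACAAACCGTTGGTTTTAACCTGATTTCATAA
>gene0002
ATGTCTCTTCGTCTTCGCGACCTTCTTGTCTCTACTGTCTACCGACGTTCTTACCGCGAAAAACGCGAACCCACTCGACT
TCATGGACTTCCCTACGGATCTGGCGCCGATCTAACCAGGTTCCAACCGAGGTGGAGTGTTGTTCAAGGGTGGCCAGCAT
GTACGATATGCCCTGTGAGCGTGGCCAGTGTGAACCTCCTGGCTCCACCTTTCTTTTTATGTGCTCCGCAGTCCGATACA
GGCAGTTATGTAGATAACCGGTTTCAGGAGGAGATAATTGCTCCAAAGAACTTCTATCTGGTAACCGCAGTGTATTCGGT
AGAGGTATGTACAGATCCTGCTTCATTGGTTGTTCTAGATTCGATGAGTGTGACGGCCACGCAGAACGAGGCATTTACGC
TGAGTCTCAACTAG
>gene0003
ATGACCAGATTGATTATGATAGTGGGCCCTCTGCCGCACAGAAGCTATGAGGCCTCGACAGGTTGTCAGAGGGTGAACTG
GTTCTTAGCTGATCCTACGTCCACGCTGGTGGGTGGTCCGTTTACCGGGAGACAAACCATCTTGCCAACAGCCGCTCCAA
GGAACGGGGTTTGCTCAGCCAGAATCAGAGTTTGGCTAGTGACCACCGCAAGGTTGATGGCTCCGATATGTGGGAAGTGT
TGGATTAGCGCATTACAAAGATTGCTATTTGCATCCGAGGGCGTTATCAACGTTGTATGTGTTGTTCAGATTGATATTCA
AGGCCACGGCGCCAACACAGTAAGCAGTCCGGTGATGTGTCGGCGGCCTGTGATACTGTCGACAACCAAGGGGCCTTCAA
GGTAA
>gene0004
ATGGCGGACCATGCGAATCGATACACTACTCGACGAACTGAACCCGACAATCCCCATAATGTCCCCCGCCGAGAAGCGTA
CTCTGTCCATAATACTCATGGACGAGCGACTTTGGAGGCTTCCTTTGCTCTATATCAAACGGCTTGGTATATCCAGTCCT
TCTCCCTCTTAACCCTGCTAAGTAGGAAGACCGGGTCGACAGGTTGTTATATTGGGTCAACAGGCAAGTGCAAGTTTTCA
CCGCTAACCTTCAGCGTAGGCTCCATCGCTCAGACGACGCTCGTTTTGACCCTATTACCTAGGTAG
>gene0005
ATGACCCGGCGGCCAGTGATACGGTTAACCATCGTAATTTTATTGGTAGTGTTTGTGATTCGGACATGGGGCTGGTCAGT
ATCACAGGCAAGAGCATGGTGGCGGCGGCCGTGTCACAGTGGCTATATCTCATGGGTGATGTTCGCCAGCGAGGCAATTG
TTTGGCTATTCGCATCACCTGATACGTTTTTCTGTTCCACAGAGAACTTCGTGAGTCTGATGCGGATCTCACGGTCCATG
CCGAGAGCACAACCGCAGATCCAGAGTTCCACAAGATTTAACAGGGTACAGCGGGCTATAAGGCAGTTACAGTAG
>gene0006
ATGAAGGAGCTACCAGGTGTAAAGAACACGCTATCGCACTTTTTGTCCGTAAGGACCAGACAACCGCTAGCCGTATCGAT
TTGTAGCGCAAGAACGCTCAAGGTTACCTTACCTGCCATCATGTTTACGTGTCTGAGTCCACGGGGCCTCAAGATTTTTC
TCACGCTCATGATGTATAGTTCCCTCAAGTGTTTCTGTGATGATGGTATTACAGAGGCTATCAGGTTATTTTTCCAAAAC
TCCAGGGATCTCGATCACAGGCTAGCCTTGTCAATCGGGATGCCAATTACCGCACTGTCATATCGGATATTAGCAGTGCT
GACACTACAATTAAACTCCGGGATGTGA
>gene0007
ATGGTACAGAGTCTATTAGCAATAAACTGCCTAGAGTCATGCGCCCAACACCGGATCACCCCTAACGAGAACTCCATTTT
TATTCTAATTTCAGGCGATAGAATAATTAGATGCGGGCAATATCTCTGGCCAGGTCGGTCAATAACCTATCGGTCGGTTG
AGAGAAAGTCCTCCTTGTGGGATTTCTGCAGGTTCCTCTCATGTGCCCAATCCCCGTGTGGCATGCTACTCGTTTATTTC
TGTAGTTCGTCCTCGGCCGGCGGCAGTTTCCAGGATTATATGGTTCGGAGCCCATCGATGGAGCAAGTTATGCTATGCAG
GCCATGGATATTATCGAAGATTTAG
>gene0008
ATGGTCCGACGCGCGCCCCATTACAATAAATACACTCTTGTCAATCGAGTCGTCACTCGCCGTCGACGCGCGGACAAAAA
AGCGTACCGAGTCCTTATTATCTTATTGCGGCTCATACTATCGACAATTGTTAGCTCCGCTACATGCAACCTACTCACAG
CCGAGTTTTGTGTTTGGGCAGTAGTGTGCCGGGTAATCACGAGCATGATACTCTCCAGTCCGTCAAACCAAACCACATTT
TTTTGTTCAGGCGAGGTAATGTTGTGTTGTGGTGCCGTACAATTGGTTAACCCATTAGATGTACAGCTGCTGAGAGGCTT
TGGCGTTCAAATATGGATCTTCGCCCAGCTGTGCCGGAGAAGCACGACGTCGTTGATGAAGAAGGTGAGCGCATGCTAA
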