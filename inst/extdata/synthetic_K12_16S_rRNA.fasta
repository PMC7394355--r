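>synthetic_K12_16S synthetic stand-in for the E. coli K-12 MG1655 16S rRNA gene; real conserved 3' segment at 1485-1542, remainder random (seed 42)
AAAACTCCATGTGTAACTCCGGAAGTAGAATCTTGCACTCGGCCTTTCCATATCTCGTGAACCCCCTGCA
CGCCCTAAAGTACAATTAGGATATTCATCCCTACACTGTATATGCCGAACGTTCTAATAAACGACTTAGC
AACAAGTCGCCTAGAAAGGTACCGCTGGCATATCACGCCTCCCGCTTGCCGTCTTCAACTTCATGACCCT
CGTGCATCACAAAGCCTCAAGCCGGAGTCTAGGCTTTGAAACAGCTGAATAAATCGTGTGAATACGTGAG
TCGTCGGAAAGCAGTTGAATATCTAACGACCCCTGCGCAAGGACACACTAGTCGCCCTTGAGAGCACTCC
AGTCCAGGCGAGGTATCCACGACGATACGACTCGGCTAGCAAACGCGCGGTTTATCTATGCAGCTAATAT
CCTTAGTAGTCGACCCCTGAGATGACCGGTCATCAGGCGGCATCCGACGCACCAACGGCTCCTACAGACT
CGTGCTACCGGACCATGCGACTCGAACATCAGATGGACAGACCTCGTAATAGCCGGGCCATGTAACACTG
ATGTCTCCGGGCAGCTCATGACGAGCACCAGACCCGAGAGTTCCTGTTAGTTTTGGTTAGGCACGGAACG
CTATCGAGCGCGTAAGCGCCAACCCGCATTTACGAAGTACCCATCGTATGTAATAAGACCTCGAGTACGT
CGGGACGTTGGCTGTGATGTTTTGATGAGCGAAGTTCGACGTTGCCGATGTTTACCCTAAGGGAGACGAC
ATCATCGCACGACTCGTCATTTGCATCATCTCCACTGCCCCGATGTCTGCTATGGACGGCTTCACCTGAT
GTGGAGCGAGGGTACTGATAGATATACGACAATGCACGTAGTCTCGATACGTCATTGGTACGAACAGTTC
GTATTCCCCATGTCTGGACCGACGTTAAGCTCATGTCTCAGGACGGAGAATGCAGCCCAACAGCTTGGCC
GGATCAAGCAGGATGAGAGGCACTTACTTTCCCCGCTACGATGCTTTGCACAAATTCTACCGCATTGATC
GTGGATTACTAGTTTTGATGGCATGGGTAATGGTGGAGCCAAACATCCAGCTAGCAGCTGCAAGCTTTGC
CTACGTGGAGTCTCTGTGAAATTCAGAGATACGCAGCTAATGGCCCCGCTTAACGGGTGCATCGGCACAG
CCTCGTGCAGCCCTCACAAATTTCCGCCATCAGTGATTCAGTATTGTTTCACCGCAGTTACCGTGAAGTG
CCGCCATATACACAGGTTCATGCTAGAGAAACTGCCACCCGGGCTTGCCAACCGGCAACGTGGCGTTGAT
TGACAGAGCTTCTTAAGCCGCTGATGTCCAAAAACTGAGTTAGTTCGAGATAGTTGGATGTCGCACTAGA
GGGAACAGCCATAGGACCGATACAGACAGTTCAATGGCGGATGCCCGCACCTGTATACACCTAGTATGTA
AAAATTGAATACGATGGGGTGAAGTCGTAACAAGGTAACCGTAGGGGAACCTGCGGTTGGATCACCTCCT
TA
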