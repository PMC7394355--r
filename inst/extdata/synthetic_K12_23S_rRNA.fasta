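>synthetic_K12_23S synthetic stand-in for the E. coli K-12 MG1655 23S rRNA gene; reverse-primer binding site at 461-480, remainder random (seed 42)
GAGGGGCACCCTTTTGCCCTCCCACTGTCTATTCCAGGTCGCCGAATATGTCCCGACTTCGACCCGTTTG
GTAGGCCAGGGGCCTGGGCTAAACACGGCCTTCCCGATTGCCATGAACTCGTTTCGCCTTAAAGTCCAAC
CGTAAAGAAGCGACAGCGACCTAATCCGAGCTTTATCTTTTAAGCGGGCGCGGGGATGGAGTCTAAGGCA
CAGACGGATGCTCATCATATCTCGTAGCATTCATAATGTTGTGAAAAACGGATAGGCTGGGTCAACAGAT
ATGTGTGGTAGAATTACCGGCAGCTCTTTTGCCGGTGGGTGCCCGGCGACCCGAAACTCGGATATGCATG
GGGGAGGGCCACCCATTTATGTGCGAGCTGGAAGACGGTTCAGCGGTCCCTCTTTGGATCGATTCCAAAT
GACTAACTACGAGACGTGAGGCGTATAGAAACTTAGCGCCCCGTGAGGGAAAGGTGAAAAGTAGCAGAGG
AATCAGGAGAGGCTGGTAAAACTAAGTGTGAAGTATAAAATGCGGCGCAGTTTGGTAGACTCATAGTATA
GGACGCATACTCTGAAGTTCGAAGCGGTTCCTTTTTGCTAATTAACCAACAAGCCACGAGAGTTGTCCTC
GTGTTTCGCAGGGTAAATGGACATTTGCGGCCGCCGCTCATGCTCGATATGAATAAGTTCAGTGGGATAC
CATCGATCAGGGAATCCCTAGGCCAGCGGATATCACAATCCCTGTGGCACGGCATGGTGGGCTCCCCTTA
TCTTAGGTTTAGTAGCACGCTGATCCGCTCGATGAGCAAAAGACCGACGCAGTCCGCGCTTCATGCAGCT
AAGTTATTATTAATCTTTCTCCAGGTTGGCTACGCTACCGTTCGGCAAACATATTGCTGCAAGATACTAT
TAGGTGGCTGGACTTGGGCTAGTGGCCGACTGCTAAGTATTCCCGTTTCAGTATACTGACACGTGAATCC
ACCAGGGAAAACCTTAGTAGCGGCCCGGTATAGCCAGCATAGGGTAGTAAGGGAGGCCATCAACGATCGT
GCGGTGTGGAATCCCAGAGAGGGTAGGAGGCTAAAGCTGTTGAGGGTAGGACTGACAGTGTGAGCGCGAA
GGTCGTGTCTTCGTTAGGCTGACGCACTATACCACGTCATACGCTATCATGAATCTTCCTTGCTGTTGGG
CTAAGCGGGGATCGCTTACGAGGTTAAATCCCGCTCTTACAGGGAAGAGAGAGTCTTCCTTACTCGAGAC
CCATAGTACTATGATTTCGGGCAAAGAAGACGGGACCACTAATATTTGACGGCTCCAATCTCATGATCGT
CCGGGGCATGCAGCCCTACATCGTCCCAGCCCGGCTAGTAACGGTAGATTATCGATGTAGCGTCAAGGCC
ACCCATCGCTTGACGTAACAGGCCTCGTTCAAAGCCGAATCAACTTGGAAGTCTCACAGGTTCATGCTGC
AGGCTGGGTGCCGCTTACACACGCTAAGACAAAGACTTGCGCCAAAACGCTGGTGCTAAAAGAGCTTGTG
ATGCGTACGAGGCCGCGCAAATTTCAGTTAGACACGATGACCACGAAATACCGGGGAGGTTTAGCTTGTT
TGCTTAATCCCGCCAAGTAAATAGCCCAGTCGGACGCGGCTTCCGCTAGATAACCGAACTATTCAACCTA
TCCAAATGTGGCCTAAAAGCTTGATTCTCAAGTTTCCTATTAGTCAGTCATTTGGTGAACCACCGTGGAG
GCGCATATTAAGAGTATACTATCGAGGAATTGCTGGATGGATACTATATTTCCAAAACAGCACTGTATTT
GACGCCGCTATGGCCCTCGTGGGTGACATGCTGGGTTAGCTAGCCGGGCAACAACTCTTAGCGTTGAGTC
GGGCTCAGAGTTGCACCCGTTGGCTGGGTTAAATATATCACACGGCAAGCGATGCGTCATGTAATAGGTG
CGGAACTCCAGATTGGCGATGTGCAATTACTGTGCGACTTGTCATATCTACAGGGGACTCCAGAATATCA
CGTACTTCCCAATACCCAATATCTTGCAACCAAGCGTTTAATCACCTGTTAAATTGTGTAGAGTAGTAAG
CAGATTACTGCGGAGAGAGAGCGCGAATCTATACTACGCTCCGTCTGGTTACCGTTGCCTGGTAAGAATG
ACTACGGCCTAGAATGGGTCCACACCCTGCCTCCTAAAATTGCACTGAGCAGCAGAGCAACGAGTGACAA
AGCTGGGAGCCCCCAATAGAAAGTACTGGATTTCTATGCCACATGGGACCGGCCAATACATCATTCTGGA
ATGTTCCAATGTTGCTTCGGGATCATCTATCTTGGGCGGATAACATACGGGTACGTGCCTTGGCCGTCCT
GCTCACGTGCTCGACGCTTACCGACATAGCTAAGACGTGCGCTGAGGTTACTACGTCTGAAATTCCCCAG
CGTTAACAATTAAGACCGTTATGCCACTAGTGTAGCTTACTGATAATGACAGGTACTAAAAAGTGCAATA
CCATCACGATCTATCATAGGTGTCATTGTAAAATCACGTCTATAAGACCTTTTCTGCTCTTGTACGGGTG
CGATTAATACGTCTTCGGCTTAAAACCGCATCACAGCGTTGTTCTCCAAGATACAGAAGGTACCCTTCAC
TATTAATATAGAGTCTGATTCCCAAGGTAATTAAACACTTCTGAGACTTGTAGACAATGCAGTGCCTCAC
CTAGCATCGGTTGTCCGCAACAAGAGGCTTCTTGCATATGAAGAGTCTTCTCAGCACTTGTGTTTACTGT
TAGGCTGTCCGTATAAAGCTGCGCTAGGTCGAGCTCTCGTCCTTCCAGGCAGTACCAGTGTCGTGCGTGC
CCCCGTGGTCGGATTAACTCACCCTTATCAAACT
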