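>mock18S_1
ACGGGACAGCAGGAATAAGCATAAGATCGTGACTAAGCAGGTGTCAGCAGCCGCGGTAATGGGTCGGTAA
AGAATACGATTAGCACCAAGTAGGCCAAAGTCTAATGGAGCAGGATGGTTGCCCCTGGTTGATTGTTTTC
CACAAAGACGTGCCGCTCTATCAACCTCAGACTCGCGTTGGTCTCGCAGAAGCTCTGCCAATTTAAACGG
GCGACTGGCTGCGCGGCAGGATAGAGTCTTCCGATGCTTAGCGCGAATATAGCCGGCGAGCATGCCTACA
GCATTTTAGCTTGAACCGCTGCGGCTTGGTCATCACTCTAACGCGGCCTAGTACCTAGCCGGATTCAGAT
AGTTTGCTTACTGCTGTTCACATAATGTCGGCAGTGTAAATCCTAGCCAGCACCGCTGTCGGCGCTAATG
GTGAAATTCCGCGCCATTCGCATAATAGAACCCTGCTGTCAATTGTACCACCTACACTCCTTGCGGTCCT
CATCAGTTTTGCCGTAAGCCAAAGGAGGACATCCCATACCTTTAAATAGGGCGTTACCAGTCTGATTCAA
TGGGTTGCTCATAACCGGCGGATGAAATCCCACCACAAACTGTTTTGGTGGTAGTAGGCACTATTGTCTC
TCGATGTCGAAACTCAAATAAATTGACGGCGCCTTTCCGGTGTCTGCTACTGAGGATTGAGATGGGCGG
>mock18S_2
CTTCGATCAGAATCCATGGACGCGGTTCAACGCCGCAGTTGTGTCAGCAGCCGCGGTAACAAGTCGGTAA
AGAATATGGTTATCACCGAGGCGATCTAAGTCAAAAGGAGGAGAATGGTTGCGACTGGTTGCATGTTGTT
TACAAAGACGTACCGCTCTGGCAACCTGAGACTCGGGTCCGTCTCGCAGAAGCTCTGCCAATCTAACCGC
GCGGCGGGCTCCACCGCAGGACAGATTCTTCAGTTGTTGCACGCGAATAGAGGCGGCGAGCATCCCCACA
CCGTTTATGCTTAAATCGCGGCTGCTTGGCCAGCACTCTAACTCGGCGTAGAGCCGCACGGGATCGCGAT
CGCTTCCTTATGGTTGCACTCGTAATGCCGCTAGTGAAATTTCTGGCCCAAGCCACAGGCTGCGCTAATG
TGGAATTTTCGGTCCATACGGATATGAGCGCCCTGCTTTTAATAGTAACACTTACACCCATTGAAGTCCT
CAACATACTGGCCTTCACCCAAAAAACCAAATCCCGTAACTTTAAATGGGCCGTTACCAGTCTGATCTCG
TGGGTCGCAGATAGCCCGGCGATGGCCTCCTACCACAAACTGTTGTGTTGATAGTAGGTACTATTTTGAC
TCGCGGTCGAAACTCAAATAAATTGACGGATATATAGAACCTTTTGATGAACGCCTCCAAAACCGTCAG
>mock18S_3
TGTCGGTCCACCCGTATAGCAATCGAGAGCGCCCCCGCTAGTGTCAGCAGCCGCGGTAACGGGTCGGTAC
AGAATATGGTTAGCATCGAGGAGGCCGACGTCTAATGGAGCAGGATGGTTGCTCCCGGTTATATGTTGTC
TACAAAGAGGTACCGCTCTACCAAGCTGGGTCTGCGATAGGTCTCTCAGAAGCTGTCCCAATCTAAAGGG
TCGGCGGGCTGCGCGGCCGGAAAGAGGATTCAGTTGCTCAACGCGGATTGAGCCGGCGACCATCTCCGCA
TCGTTGAAGCTTGAACGGCAGCGGCTTAGCGAGCCCGCTAACTCGACGTAGAGCCGAGCCGTATTCAGAT
AGTTCTCTTACGCTTATGCTTATAAGGCCAGCAGTGAAAATTCTTGCCCGGCCCGCAAGCCACGTGATTG
GTGAATATCTGCTCCATAAGCATATTAGATCCCCTCTTTTAATTTCACCCCATACATTCCGTCCGGCCCT
CTTTAGTCTGGCCTTCACCCAATGATCCGCATCCCGGAACCTTAAGTGAGTCGTTACCAGTCTGATCCAA
TGGTTCGCTCATAGCCCGCGGATGAACTCCCACCACAAATTGCTGAAGAGATAGTACGTAATAGGTTGTG
TCGCGGTCCAAACTCAAATAAATTGACGGGACGATCGTTCATGCAATTGGACAACGATCGGCAGTGGTC
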