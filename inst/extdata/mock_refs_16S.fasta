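>mock16S_1
AGTTGGGAAGTCTCAGTTTACAATCTTTGTTGCAGGGATAGTGTCAGCAGCCGCGGTAATAAGGCAGATA
AAGTGATTTAAGCCGTGTTTTCAAAAGGAAGCATTGCCCCTAAAAACTCGGAGCCGTACCACGATACAAC
TCGGAGCAAGTTAATTTCGTACAACTAACCCCGCATCGCTTTGGAACAGTCAAGGATCTGGCTGTACCCC
CTTACCCAACTACTTCGCGCCTCGAAGGTACAAATCACGTTAAGTCACGAATCGGACCAGACCCTTCGAG
TTCTCGTTAGCACCGGTAGCGACTAGAAACACTACAATATTCGTGCTAGCGTACTTGAGCGCACGTTCGG
GGGTATTCAAACTGAACATGTGATGACATCAAAGGGACTAGATCATTCCCCCACCCGATAGAAATCCAGT
AAAGCGACACAAAAACTCAAATAAATTGACGGGCATCTGTAATGTGATTTACATACGGTTAACACTGCGG
CT
>mock16S_2
ATTATGCCTAAGCGTGAGGATACCAATTGTCACCAAGCAGGTGTCAGCAGCCGCGGTAACACGGCGGATA
GCGTTATTTAGGCCGAGGTTGGGGAAGGGAACATTCAGCATAAAAACTCGCAGCCCTACCACCATCGATT
TCCGAGCAAGTTCATTTCGTACGACTTAGCCTGTATCGGTATGGAACAGTGGAGGATCTGGGTATACACC
TTTACCCAATTACTTAGAGGCTCGAATTTACAAAACACGAGAAGACTCGCATCGGTCCGGACCCTTCGAG
CTCTCTTCAGAAGCAGCCGCGACTGGTGATCCTCGAGTCTTCGGCCTAGCTTACTTGGTCGGACGCTCGG
TGGTATTCAAACTAAACCTATAGCGACAACAAAGGGACTAAATCATGCCGCTACCAGAGGGAAATACACG
CAAGTGATTTAAAAACTCAAATAAATTGACGGGAGCTCCGCTTGTGAAGTGTTATGAGCGGTTAGAACCA
TA
>mock16S_3
AGTTCTGAAGATCGACTCGTGCTTGGTGCGCAACTATATAGTGTCAGCAGCCGCGGTAACACGGGGTATA
ACGTTATATAGGCCGAGGTTGCAGAAGTTATCATAGCCCCTAAAAACTCTCAGCCGGAGCACGATCGATC
TCGGAGCAATTCAATTTCTTACAACTAAGCCGGTATCGTTATGAAACACTCAAGGATTTGGGCACACCAC
CTTACCCCATTATTCCGAGACTCGAAGGTCCAAGACACATTAAATATCCCGTCGGACCGGACCCTTAGAG
CTGTTTTTAGAAACTGCCGTGGCTGGAGTTACTACACTCTTCGTGCTAGCTTACTTGCACGGACGTTCGG
AGGCATTCTAACTTTACCTATGGAGCCAACAAAGGGACTAGCTCATTCCACTACTAGATGGAAATACAGG
AAACCGCTTTAAAAACTCAAATAAATTGACGGGGGTTGTTTGTACACGCATCGACTGAGAGATCGGTAGG
AA
>mock16S_4
TAAGACCATGCAGTCTAGTGCGGAACATCCTGCGGGGCCCGTGTCAGCAGCCGCGGTAAATCGCCTCATA
AGGTTATTTAGGCCGATGTTTCAGGAGGCATCATTGCCCCTAAACGTTGGCAGCCGTACCAAGATCGATC
TATGAGTAAGTTAATTTCGTACAACTAACCCGGTATCGCTAAGGAAAAGTCATGGATCTGGCTATACCGC
CTGACCCAATTACATAGATACTCGAAGGTACAAAACAGGTTAAATCTCGAATCGGAGCGGACCTCTCGAG
CTCCGTTCAGGACCGGCCGCGACTGGAGCTACTACTGTCTACGTGCAAGCGTACTTGAGCGGATGTTCGG
ACGGATTCAACCCGGACCTATGGTGCGAACTATGGGACAAGATCATCCCACTACCTGATGGAAATCAAGC
AAAACGATTTAAAAACTCAAATAAATTGACGGCCATCGAGCCAATACGCATCTGACCGATTTTATAATAT
CC
>mock16S_5
GGGACGTGGCTTTACTGTCAATTGACAATGCGGGAGCTCAGTGTCAGCAGCCGCGGTAAAACGGCGGATA
ACGTTATTTAGGACGTGGTTTCAGAAGGCATGATTGCCACTAATCACTCTCAGCCGGACCATGATCGATC
CCGGTACAACTTAATCACGTACTACTTAGCCGGTATCCTGAAGAAGCAGTGAAGGATCTGGCTATACGCA
TTTACCCAATGACTTAGATGCTCGCAGTTACAAACCACGTTCAGTCACACATCGGACAGGACCCTTCGAG
CTCTCTTCACTACCTGCCGCGACTGGAGATACTATAGTGTTCGTGATAGCGTAGTTGCGCGGACGTTCGG
AGTGCGTCAAGCCGAACCTATGTTGCCAACAAAGGGACTTGATCATGCCTGTACCAGATGGGAATCCAGC
AAAGCGATCTAAAAACTCAAATAAATTGACGGATCTTAAACACTATGGTCATTGGTGATGTCGGGGAAGG
CG
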