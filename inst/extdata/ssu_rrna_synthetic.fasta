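>ssu_16S_synthetic_1 synthetic SSU rRNA reference
CGGAACGACCGGCTGGCGATCGGATACCGTGGCAGCTGGTTCGGTCGGCCCTCGGAAAGCGCGGCAGTAG
CTAGTGGCACGACTCGCGAGTGTGGGCCGGCGATGGAGGAACTCCGCGAACTACCGGAGCACGAGTTTAA
CCCGCGAGCCGAACACCTCATCAACGGCGCGGCACGAGCAGAATGTAGTCATTACCACAACGCAATTGGT
CCCCATGGGGTTTTATGATTGTCCAGAGGGGCCATGCTGCGTCGAGTGAAATCACGGTGTTCCCAGGGGG
CCATACTCGACCGCTTTCACCCTTGGAGGGACAGATAATACACCGCTCCGTGTGAAGTTAGAAAGGTGGA
GGTGGTGATGGAGTCCGAGATATCCGAGTGGGAGGGCGCAGGGAGACTTCGGGGTTGATGGAGTGGAGGG
CTGGGTAGCATTCAGGCGCTTAAAGGAGGCGTAAAGGTGAAAACGGGTACAACTGCCAAAGCTAAAGACA
GGCAGCCTGGGGCGCGGAGCGAGTGGAGGGCGTCCCATGCAATCGGTTTGCTAAGTTGTACATGGCGGGA
GTTTAGCACAGTCAGGATTAAGTACTGACCCGGGCGATGGAATGCGGTCGAGGATGTAAGTCCCCAGGCT
ATCACGTCTGGAAGGAGAGGCCGGTTAAGGGGCCAGAGTAGGTCTCCGGGTTCAGGTGCTCTGCTTATCT
ATGAAACAGGCGCAATACGTCGCGTGACGCGTAGCTTGACGCCGTCCGGGCTTATGCTTAAGTTAACCCT
CACAAAGGCGCGCGCACAATACGATATGTAGCTTAGGTAGGTTAAGCCTCTTTGTCACATGCACGGGAGC
AAAATATCTTCAGGTTCATGGACGGCGAAACGAAAAAGACGTGCGACCGAACGAACCCTTTGAGAGAGGG
GGATCAGTGTGAGCCGATAAAAGCGAAGTGCAGTCGCAATACGTCTGGGACGGGCCGGTTGTGTGGTGGC
AAAACATAATGTCCACCTACTTAGATCCGGATAACTAATAATTTATTATAGCTGTTCGTAACGCCAGACA
GCAGGTATGGTCCACGAAAGGCGGCACGCAGACGATCTTATGCAACTTCTGGCAGCGACGGGCCAGGCCA
GTGTGGCAAGCCGTGCAGCTCAAGTTCCAGCTAGTCCCGGCACGCGGATGGAAGTAGATTGACACGCGCC
CGATCTTGTGAGCGGGGGCGCATGCAAGCGACGGATAGGTATGACAACGAGTTTCGCCAACCCCACCATT
AATCCGACGGCGTAGCCCGTTCCTCACGGCGGGCTCCGTGAAAAAACTGACACCCGTCCTCAAGGCGTAT
ATATGACATCAGCGGGAGATGGATCACCGGGCACCCGTGAGGTGTCCCCTGTGTAGGGGGTGCCAAGTGA
GGCGCATGATCGTCTGGGCATGTTTCGCTACTCTCGGATCATTCCCTTTCGACATCGTGTAAATGTAATT
CCGGCGATAGCCTATGGCGGCGCCCAGATG
>ssu_16S_synthetic_2 synthetic SSU rRNA reference
TGATACTCATTTGTACACCGGCCTAGGGTGCCGAGTAGTATGGTGGTCCGGCGACGAGACCCGGGTACGA
GTGAAGAGGTGGGGGCCGGAGGATGTTGGAGTCCTTATGCAAATGCACTAAGCGTATTAGAGGAGCGGTC
TCGGTAATCGCGGTCCGGTGGATTGGCTTCTCGTTTAAGGGGCGAGGGAAGTGCAGTGCACCGATGACCG
GAGATTTAGGCCCGCGGTACTAGCTGTAATCAGCATCGACAACGGGCATTGACGTACTGCGGAGTCTGGA
GGACAACGTAGCACTCGTTGAAGCAACCAGAGGACGGGGAGTCCGCTTGTGGTTGGAGGCAGCGCACAGT
CTGCTACGATAGCGGCGACACGGATGGAAAACAACGTCTGGAGACGAATGATACAACGATCCTGTCTACC
ACATTCTAGCGCGAGAGAATAGCGGCACGACGTGCGACGACGTGAAGTAACCCTAAATTCTCCGAGCGTG
AGGCCCCTCGAAAGCAGCGAGGATCGAGGAAAGAATACCGCAGCCCTGAGGGGTGAGTCTAGTCTAGCTG
CATGGGGACGCTCAGGCACGCGCGTCGCAGGCCCGCACTCCATCCCAGAGGCGGGCCGGGCTAGATCTCC
GCTGTTTATATAGACTACCCTATCCGCGTACCTAGTGCTGGGTACACATCTAGAGCAATGGAATAGTTCC
TACCCGCGACGAGACACGCGTGCCCGCCACCCCAATGCGTGCAAGGAACAGTAAAATCAGTTGCGATACT
TAGGGGATCCGCTCCCGTTCAGGGAGGATTGGAAAGAGGCGTGGTGTTGGACGCCGATCGGTCGGTAGGC
GGGAACTTAATCAGCGAGTCACGTAGGTCACCGGCCGATTTCTTCCCATGTAGCTTTTTGGGCCACACCA
ATGAAGGCGAGCCACCAAGGTAATCGGGGGTGAGAGGCGACCAGGACTAGCGGACCATGATGGGGGCGGG
ACCACCCTGTCCGGCCACCCTGTAAATTAGGTCCTAGGAGCAGCTGTCCAGGCCACCGATCCGGGAAGCC
GACCGCCGAGCACGTCTAAACAGGCGGGCTGCATATATACGTCGCGTGACTCCGCCTTAATCTGTACGCT
GGATAATCCCGGTGCCGACTATCCACTTGTCGCACAACGATGGAAAGAGTACTAGAGCGGATCTGGGCTT
CAACAACGGGCGAGGGTGCCTTTGGGGTCTATAGGGTTGCTTCTCTCTTATGGTACCGGGTCGGCTCAAC
GGCGATGTCACACCTGAGGTGTGCATGTGCCGACCTGTGATGTGAAGGTGACAATTACAGGCGAGCAGTG
ACCCCTGTTCTACCGTATCGTAACTGGTCGGTAGTGATGCAAGCGCGGACGAAGGTCTAGGCGTGGGACG
CAGACAGGCCCCTAACTGGGTGGCTGCGTCCAATGAAGTGTGCTATAATCAAGAGAGTGGCCTGTCTGGT
CGTCCATGGCAATGGTATACTAACCTGGCG
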