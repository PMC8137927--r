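>SYN0001
AACGACTTAGCAACAAGTCGCCTAGAAAGGTACCGCTGGCATATCACGCCTCCCGCTTGCCGTCTTCAACTTCATGACCC
TCGTGCATCACAAAGCCTCAAGCCGGAGATGCCTCCGTACTCGCGCTATACCACCAACTCCAAGTCTCCAAACTGCGCCT
TAAGCGCTACAGAATACGCGGATGTAGGCAGACTAAGTCATAGAGGGGAGCTAATTGCACGTTGGGTCACACGTTCTAAC
CACCCTTACCACACAGTCGCTTGCGCTCCAGATTGTGATGCGGGCCACCGGATATCGTCTCAGCTTATTTCTTTGCTACA
AGGTAAATAATCTAGGCTTTGAAACAGCTGAATAAATCGTGTGAATACGTGAGTCGTCGGAAAGCAGTTGAATATCTAAC
GACCCCTGCGCAAGGACACACTAGTCGCCCTTGAGAGCACTCCAGT
>SYN0002
CCCCTGAGATGACCGGTCATCAGGCGGCATCCGACGCACCAACGGCTCCTACAGACTCGTGCTACCGGACCATGCGACTC
GAACATCAGATGGACAATGGCCGGCAGACCGCGCTCAGGAAGGCAGCGTCCAGATGGCCCCCGATCTTTCTACCTCTTCC
CAGGTCCAACCGTGGGAAGCCCTTATTGCACGATCAGTTCGTCAAGCTGTCGAGCAAACGAGGACCGGGTCCTGCGGATT
GATTGGTCGCCTGCCTCCCCACATAGGTTAGAATTCATCCGTGAACTAGATGTACTTGCCCCCGGTTTTACGGGTACACT
GCTTCACGCGAACTAAGACCTCGTAATAGCCGGGCCATCTAACACTGATTTCTATGCTATAATCATCACGAGCACCAGAC
CCGAGAGTTCCTGTTAGTTTTGGTTAGGCACGGAA
>SYN0003
CGAAGTTCGACGTTGCCGATGTTTACCCTAAGGGAGACGACATCATCGCACGACTCGTCAATGTGGCTCGGGGTAGAGGG
CTCAGACGCGTCCCCATCGGGGTTAGGGCGCGAATCGACCTTACCGGGCGGATTGGGTTTGGTACACGTGCCAGAAAGGG
CTGTAATCAACGCCGTAGAGCGTGTAATTTCAATTGTAGTAACTTGTTTTTGCGTAGCCGCCACTTTACTGGCACCGGGA
AGCTTCTTGTTAAGGCGGCCGGAACCCATGAATTTGGCGGGGAGCACTCTGCGTGAGGTACATTGCTGGGTTACTCTTAA
GGGAGTTAGGATAAAGTGATTTGCATCATCTCCACTGCCCCGATTTCTGCTATTGACGGCTTCACCTGAATGTCGTAAAG
GGTACTGATAGATATACGACAATTCACGTAGTCTCGATACGTCA
>SYN0004
CAACAGCTTGGCCGGATCAAGCAGGATGAGAGGCACTTACTTTCCCCGCTACGATGCTTTGCACAAATTCTACCGCATTG
ATCGATGGACGGAGAGCCTGGTGACTTCCCTTTTCGTGTTCACCTCCCCCGCTACCATCTGGCTCTCACTTCAGTGCGAT
TAGCCGAGAAACTCGTGAATCGTGGAGAAGGGACCCATATCAGACGTCTGCCTACCGGTCCCTACAGGTTCAGACACGGG
CAGGAAGGGTACTACGCTAGGTATGAATGCGCCAATTAGTGGATTACTAGTTTATGGTTTAATCGTAATTGTGGAGCCAA
ACATCCAGCTAGCAGCTGCAAGCTTTGCCTACGTGGAGTCT
>SYN0005
CATCAGTGATTCAGTATTGTTTCACCGCAGTTACCGTGAAGTGCCGCCATATACACAGGTTCATGCTAGATGACATCACA
AGGGAAACCTGAACACAAGACAGCGACCATTATAGAATGGTCATATAGCATCGGCTGCGACATTTTGGGACAAAACATGC
CGCGGGCTAAGGACTACTCTAAGGGGTTAGCACCCGAAAAGATCGCCATTAGCCGGACTCCGTCTAGAGAGGACGCCGAC
GTTCTCCGACTCAGAGCACAAGGTCATGATGCCGACAAGACATAGAGAAACTGCCACCCGGGCTTGCCAACCGGCAACGT
GGCGATGCTCTAAAGAGCTTCTTAAGCCGCTGATATCCAAAAACTGAGTTAGTTCGAGATAGTTGGATTTCGCACTAGAG
GGAAC
>SYN0006
GTCGCCGAATATGTCCCGACTTCGACCCGTTTGGTAGGCCAGGGGCCTGGGCTAAACACGGCCTTCCCGATTGCCATGAA
CTCGTTTCGCCTTAAATGTGTTGTCGGCAGATACACAGCAAGTACCGTCCAAGCGAAAGGATAGTCGTAACGGCTGATAT
CACATGTCATTCACCGGTCCAGGTGTGTGTTAAGAACGCCGCGAGCGTAGGCGGCCGTGAGCCTTGTTCCTACTATCAAA
GCGGCGCTCGACCGATAGCTCGGTCCGCACAATGTCGAAGAGCTCGTCAGATAGAAAGTAAAGCCCAGGTACAGGCACCG
CGGCTGCCCATAATCGTCTCTTCCGGTCATACTGGGATCAACATCTGGCTCAGCAACTCGGGCCTTAAGTGGGACCGTTT
TCGTCTCAGCCGAACCTGAAGTCCAACCGTAAAGAAGCGACAGCGACCTAATCCGAGCTTTATCTTTTAAGCGGGCGCGG
GGATAGAGTCTAAGGCACAGACGGATCCTCATCATATCTCGTAGC
>SYN0007
GCAGCTCTTTTGCCGGTGGGTGCCCGGCGACCCGAAACTCGGATATGCATGGGGGAGGGCCACCCATTTATGTGCGAATG
TTTAGTGTAAAATTGGTGTCCAGTGTGGTTCTGTACTACAAATTTTACAGCCTGAAGCAAAATCGAAGGGCGAGCATTAC
GGAGCTGTTGTATCCATTTCGCCTAGGGGCAGTTATAAATTCATGGGTGACTGAGTGCAGATGCATAACAAGTAATCGAA
GCTTAACGTGAGCTGGAAGACGGTTCAGCGGTCCCTCTTTGGATCGATTCCAAATCACTAACTACGAGACGTGAGGCGTA
TAGAAACTTAGCGCCGTAGCAGAGGAATCAGGAGAGGCTGGTAAAA
>SYN0008
ATTAACCAACAAGCCACGAGAGTTGTCCTCGTGTTTCGCAGGGTAAATGGACATTTGCGGCCGCCGCTCATGCTCGATAT
GAATAAGTTCAGTGGGATACCATCGATCAGGGAATCCATGGTTCGACAAGCGAGTAGGGGTGGGACAATATTCCTTTCGT
TGCCATTTTCGGCATGGCAGTTACGGCGGGGCGTGAACGTACGGAGTAATCGTACGCTGCGTGTATCAATACGCGTTAGC
AAAGTTGGAAAGTGGAAAGGTTGTACGGTGAGAAACTTCATCCCAGGTCTACACAGTCCCCGTGGGCGAGGAGAGTGGTT
GCGCAGAGAAATCCGGTCAAGTTGGTCTATCAGTCTTCATGTTCCGCCCACTTAACTAGGCCAGCGGATATCACAATCCC
TGTGGCACGGCATAGTGGGCATGGCGTAACTTAGGTTTAGTAGCACGCTGATCCGCTCG
>SYN0009
GGCTAGTGGCCGACTGCTAAGTATTCCCGTTTCAGTATACTGACACGTGAATCCACCAGGGAAAACCTTAGTAGCGGCCC
GGTATAGCCAGCATAGGGTAGTAAGGGAATGGTACTCACATACCTATACTCACTAACCACCCAGTGTGGCGTGCGCCAAT
TCAGTAACCCCTTCGACCGGGACAATGCTTTAGCAATTTCAAACGCACAGGGCCGTACAATAGAGATTGGTTGTGATTTT
GATGATTACAAACGTCACAATTGGGCTGGCCTTAGCGACCCATCAAAGCATCATAAGTCATATGTTGTAATCATGAGCAC
AAACGTCACGATTGATTTATTCCCGTATGGAATAGAACACCGAAGTCAAGATAGTGCGAACGGTGCGATCCAAGTATTCC
TAGCTTACGACACAAATGCTTTTACGCTGACTATGGGGCCCTCCAGGTCGCACGGTAGATGAGGCCATCAACGATCGTGC
GGTGTGGAATCCCAGAGAGGGTAGGAGGCTAAAGCTGTTGAGGGTAGGACTGACAGTGTGAGCGCGAAGGTCGTGTCTTC
GTTAGGCTGACGCAC
>SYN0010
AGAAGACGGGACCACTAATATTTGACGGCTCCAATCTCATGATCGTCCGGGGCATGCAGCCCTACATCGTCCCAGCCCGG
CTAGTAACGGTAGATTATCGATGTAGATGCATCTACCTCCAGCCGCCGGAACCACGAATCGCTCGGAACGCAAGGGCCTT
CTACTTGACCGAAATTTCTTTTCGGCTAACGGTAGTTCTCTCGTTGGTGTGAGCCGTTCACCTAGGACGGAGCCCACTTT
TCGAACGGGCCAGTCAGAGCCGAAATCCCACGAGGACATTCTTTTTTTAACGAAAGAGCGGAATTCCCTACTAGCAAATA
CCATCATCACGGACCCTCTCGTTGATTACATCATACGGTCATGTACAACGTTTGGGGGACGGCCAAGGGGTCCCAATTTG
AACTCTCATGTTTACCACCCTGACGAGCCACGGGGAGTCGTCAACCTATCCGAACCGAGTGTACGCCGTGCACGTTTCGA
AACTACTCTTCTCCCGGGGAAGATCCCAAGCTAACGTCAAGGCCACCCATCGCTTGACGTAACAGGCCTCGTTCAAAGCC
GATGGGTTAAGGAAGTCTCACAGGTTCATTCTGCAG
>SYN0011
CGAGGCCGCGCAAATTTCAGTTAGACACGATGACCACGAAATACCGGGGAGGTTTAGCTTGTTTGCTTAATCCCGCCAAG
TAAATGTCACAGGGTTGCCCCGTCATGCTCAGTAGTAGAGACCCATCTCGACGCTGCGCTTACAAAATGCGAACCACAGC
AATACCGACAGTCCTTTTGCGCATGCGCTTAACACGACTAGGATCATATCATGCGAGGCCTTCAAGTGAATTTGGATCGT
ACCAGTATGATCCTTGCGGTTCAGGAGGTCGGAGCCGGCTTAGGTAAATAGCCCAGTCGGACGCGGCTTCCGCTAGATAA
CCGAACTATTCAACCTATCCAAATATCGCCTAAAAGCTTGATTCTCAAGTTTCCTATTAGTCAGTCATTTGGTGAACCAC
CGTGGAGGCGCATATTAAGAGTAT
>SYN0012
AATATATCACACGGCAAGCGATGCGTCATGTAATAGGTGCGGAACTCCAGATTGGCGATGTGCAATATGTTGTACCATAA
CCCGTCGCCGACGGTACGATTGGGGCCCGTTAAGGCGTGTATTAGGATGCTATCCAAACACCTTTGTGGTACAACTCATA
GCCACCAACAACTAAAAATCGGACAGCGCTACAACAGTAAGATTCGATCCGGTCATTCAGGAAACCTGACCTATACCCGT
ATAGTTTCAGGGCCCCCCGCTTGCCATCAGAAGTGCAGTTTCTCGTATTCGGCTAACCATCCGCGGATGGTTAGTATAGT
GAGCGATGCAGTGAGCCCCTGCATGAGGATATCGTCTCCAAGAGTCGCTCGCTGGCCTTACACGCACCATGCGTTTGAGA
GTGCCCTGCGGTTCGTCGATTCTCCAGTGGTAGCGCATCGTACGGACCGACACCGCCTCGGGCTTTCCGGGAGCATTGCG
GTGTGCAGTTAATACTGTGCGACTTGTCATATCTACAGGGGACTCCAGAATATCACGTACTTCCCAATACCCAATATCTT
GCAACCAAGCGTTTAATCACCTGTTAAATTGTGTAGAGTAGTAAGCAGATTAC
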