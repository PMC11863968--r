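>chrF
AACAGAGCGAACACTACACGAATACTCAAACCATGCGTATGCTATCGCCCAACGTGATACAACTTATTGA
TTCCTCGTCGCTCCGACATCGCGTACCTCCCACGGCCCCGGAAAGTTCTTTCTAGCGCCGTAGACATAAG
GAGTCGATCAGGTCATATAGTTGATTTCTAGATCGTCTAGTTGGGGAAGCTTGTTCAGGATCGGCGCTAT
GACTACGAGGAATCTAGACACCTTAGCGAACAGGGTATAAAGACCACACAGAGATGTACGCAGAATCCAT
GGCAACGGTATAACACGTAGGTTGGTGCCAACTTCACGAGAGTGCAGGTGGTGGGGCGCAGGCAATGGGA
AGTACTCGGGTTCATAAACAGGCTTACAATTGGGAATCATGTATGTAACGAGCGTTGGAGAGAGATTTAT
AGCAGCTTCATACAATCACTCTATATCGGGAGGGGACATAATTCATTTGTCTGCGGCTATAGCTAGCTCG
TTAGATGTGCCGCATGGAAATGTAAGTCCAGTGCACCAGCCGCGGCCGGTGTGGCCGATGCTTAGTACCC
GAAATAAAGAGACCACGACACTGCCGGTCGTTGTGCTGCGCCGTCTTGTCTACGGAGCCGCACTATCGTC
TTAGGAAAGGGTCTGCCAAGGCCCGATAGAGTGACCCAAACTCTTTCAAATGCGGGTTCCGCCATGGACT
CCGGGTCGTGAGTATTCGGCTCCTGTCTGGTTCCACGGCGAACTCTCGAAAACGCTACAAGAGGGCTGTA
CCGCTGCACCGTAACTGAACCCAAACGACTATCTAGCTCACAGATACCGTAACATGTCGGTGGATTACTG
GGCGCCTCCCGACATACCGTCGCTGGACAATGAAACATCTGTAACGAAGATCTTACAACTACACTTTACG
AAAGATGCAATGTCTTCGACTTGAATGTGTAGGCCTCAAATGAGGAGCGGAAATATACGTTGTAGCGTGT
ATGTTTTTAAAACGGCCCACTTGATCGCATGGCAAAAAATTTGGTACCGACCACACCAGTGAATGTATAC
TTAGTCATCACGGTCAATTATAGCCCCCAAGGAGTTCGTTTGAGGCGGGGCAGTTTCTTACGTGAGGAAT
CGGATTTTCTTAGCTGTCAAGGAGGTGTGTTAGTACCAGCGGGTTGCGTATAACAACCGCTTAAACGTCA
CTTTTGCACTCGCTAGTTAATATGCAGGGAACCTGAGTAAAGGCCAGATACCCCACATAAGAATTAAGTT
GACAGCCAGCACAGCTGGGCGCCTGGATGGAGGAGCTAGTTTCTACGAATGATTAGAACGAGAAAGAAGT
CAGTACCAAGTTTGCACACATATCAAGACGCGTTTCAAGCTCTCAACGTCCCGCGACCTTCAAAACCTTG
GGCGTGCCTGCGCGCTATCGTGCAATAAATCTCATCTGTTACTCATCGAGATCTTGTTCGGTTCGAGACA
GCTCCGGTCTTACCCGCCTTTGAGGCGGCATAGGCACTATGTCAATCCTATGATAAACTGTAGTACGTGA
TTGATGAAAGCATCCTACTGGGGGGGTCATCAGATCACATGTGTCGCGTAGACTCGGTCGCGGATAAAAG
AGAATCAATCTCCTATAAAATCTGGGTTGTCTGCACTAGATAAAGTTTTCACCATAAAGGGTCGCACCTC
GGCCGAGATACACCTTAGCATCAGGGGAGGTCTTAGGTCAGCCCTAGTCCCCGGCAATTGAAGTTGTCCC
CACGCGAGACGACGCAGGAAAAAAACAGGTCCAACTTAACATCGAAACTCCGAATCGATTCTTCAAAAAT
CTCCTCCCAAGACTATCTTCCGGCTCTACGCAGAGCCATTGCGGCAAAATCGCGAGCGAGTGAGGGAATA
TGTTCGATTTGCTCGATCAGAGTTTAATTTATAGCTGGAGGGCATGATTTGTCGTACTCTACTCCTTTGA
CCCTAATGATAGAGGCCTAAAGTGTGCTCATACGGTAACTTGGTATGAGTCGTGCCATCGGGGTACGTAC
CTGGAGTAAGCTCGTTAATGGACTTGATGGCAGGCCGGCGCGCATGCGGCCGGCCCTGAGTATGCGGTGC
GGACTCCACACGACCGTAGCCAGTGCGGCCGTAACGGACAAGCAGGCAACTATAGATCACCAGAACGGCT
TCGCGTTCCGGCCATGACTATATGCGTAGGACGATCTGTCGCGCGTGATACGTAATCCCCTTTCCATGTT
CTACCGTGACTAGCGGGGCCGTCGTATTATGCGCCTCTGGCTAGATATCTGCATCTAGTAACCGTCAAAA
GTGGATGAACCGGTTCAGTCGCTAATAACGAAAAGACACAGGCAAGTCCGCTGGTTCGCATGTCTAGAAT
GTGAATCATTTGGTCACCTAAATTTTCAGTCAGCACAATTCCCTAAAGAGCTAACGTTCTTCGTCGCAGT
GGACATTTGTAAATCATTGGCATCGTTGGATTGGGACACCGTGTCTAGCGAGAAATGACCGTCAAGTGCA
GTTCTTGCTTAATGCAAACATAGGTCTTAGAATACTACCCCGGGCCACCGGGACGTTAGCATCCGCTTCG
GCCTGCTCTCTACTCCGGTCGGGTCGCTCAACATTGACTAGCATACACATACGGCTGTGAAGTTGGGGAC
CGGGTAAATTATCCTTGATATGCAAGTCGTTTCACAATTTTTAGGGCGTTGTTAACTAAGTTTGAGGAAT
ATGCCCCAAAGCATCTCCACGTAGCATAGTCGCGGCGTAGATTCCACCCACCTAGCTATAGCGGCAGCTC
CGGTCTGTATCACGTCTCCACTATTGGGATTCCCATTCGTCCAACAATTGGCATTATGTGAGAATACATA
TTGTCCGAGGGCGTCTTGAGCCGAGGGGCGGAAGAGTTGGACGTCGACGTGGCATTCATGACAGTAAGGA
CGGATTATGTCTACAAAAATGCAGGAGGACTGTTTCGCGCTCTCTGACGCTAATGGGATGGACTGCGGTG
AATGCGGGTTGGTGTAATGCCCGCGGGACACGGGCAGTTAACGCTGAACTAGTTCAGGCACCCAATGGGA
TCGGACATAGGCGTGCGGAGTGGGGCACTCTCCTAACATACAGACAGGACATTACAGGTGTGATGGTGAA
TACGTTACCAATTGATGTTCTCGAGCATTAATAGACCAAAGCGTGAAACAATATCCAAGGCTAACTCACG
CACTAAAGTTGCAGCCGGTACTAAGTACGGGAACCATGTGTCAAGCTGATGCCACGATCGCGGAAGCGTA
CCTAATGGAGGCTGGGGGATTCCGAACCAGTGAAACAATTTGTACGTTAACTGCAATGTTCCAGTGCCAT
ATCAGTTCCATGAAAAGTTGGGATGGTCTGAGCGCAGAATATCCACCCAGAAGGGTACTATCGTGCGGCG
TGTCTGCTTCTTTCTGTCTCACACCACCAGATTATAGTGCACCGGTGATTGAGTGTATAAAACCCACGTC
TTCAGGTCTCACTACCGTATCGGTGCCCCAGCCGAGTATTTCTCCGGACCCCGTCTACAGTGGATGGGGC
TCCATATCCACGCCGGGGATCCTGGCAGCTCGGTCCGCAGGATATTACCTCATCTACGATAATGAGGTAG
ATATCTGGGTCCTTTTAACTGTCTGGACCACATAGCAAATACGGGATGATGTAACAGACAGGACTTTTCG
GCGTGTGGCACCACCGGCGGGGCTAACGGTCTAAATTTGCACTACTGTGTCGGTGAGCGAATATGGGGTC
TGCGATGAGAATAGAGGATCCAGTTAGAAAGTCAACAGTGGCCGGTGACCGGCTAACTCATGCCTTGCAG
CCCGGAAACCAGGCATTTTTAAAGAGGCACTAGAGTGCAATGCTCCCATCCCCGTACATAACGCGCTTGA
GAACCATGCCATTACGGCGACAGCCTGTCTACATAGACAGGGGATCGGGGTACCTGTGAGGTCTGATGAA
AAAGATCGTACAATCGGTCATTACGTCACGAGGGGCCTGGTCCCCGTACCGGGGCAGATGATGATTGGAG
ACAAATACAATACCTTCACTAAGGTCCAAAATATCGTTGTACTAGGTAAACTAATGAAAGGGGGGCAACC
AGCTCTCCTACATCTAACCCTGGAATTTGCTTACCTGTTACGTTATTGGTCGCTCGGTTTTATACGTTAT
TAAGTGCGATTCGCCTAGGACATACCGGCTCGTACCTAACCTTTATCTCCCGGCCACGCTTTGACCAATC
AACTCCCCTTAGGAGGCTCACAGGAGCAAAATCCAGGACGTTGGCCCTCTAAGAGGATCACCTTACATTC
CATTGGCGCAATACGGCGGCCTCGTGCCGGAATCTCATCGATGAGATAGAGCGGATTTAGTTTCATATGC
GTTGTGAAGCCCATTGTCCAAGATCTCGAAACTACTGCGTGGCCTTCAATTGCTGATTTCGCACGAAGTG
GGTCTTAGTCATATCTAATGACGAAAGCCGATGGGTTATGCGGTTAGCGAATGGGTTGCTGATTTTCGGA
GTGGGCCCAAACATGCCCCTGGCGAGGGAGGTGCAAAACTGAACGAGCTATCCCTCCCAAGACTATCTTC
AGGCCAACTTCGTGTCCCTATCCCTCCCAAGACTATCTTCAGGGAGGCACGAGGGTCCTCTCCCTCCCAA
GACTATCTTCAGGGGCTCACTGCTCCTGTTTCCCTCCCAAGACTATCTTCAGGTCGTCCGGAGCATACCC
TCCCTCCCAAGACTATCTTCAGGTTTCGGAATTAAACGCGCCAGCCCCACACCACAGCGATGCGGGGATC
CGTCCTGGGCGATCCGAAGGACCGCTGTCACCCGCTAGCAAAGCTAGCAAGGATTCTCTCGCGGTCGGAT
ACCTTACCAGAGACTTATTCCCAAAGAGTTCGTAATTACAACGTTATGTCCAAAGGAACTACGTTACAGT
TATCGTACACACTGCGAGTTAACTTATGAGCACCCGCGTAGTCGTCATATCGGAAGAGATGCGCGTGGCC
GAGAACCACAATGTTCAAGACATGAAGCGCGAGCTGCAACTTGAACCGCGCGTGAGGTACCCATAGGTAG
GGATACCGTACCCAGCTTCGTGCAATTTAACGCCTACAGTTGTTGAAATACCATCAAATACGTACACGTA
GTTTAAATACGGAAGTAGTGCAGTTTCTTCCGTGAGGAATTGGTATTATGGACTGCGTAGGGAGTATGAG
GCGGCCGCGACGGATTGGCGCACGAGAACTCCACGGCTGTACCCCTCGATCCGGTTCCCTCCTCGCCGCG
ATTTATTAAACTTTAGTTGTTGAGTAGAGGTATAAACATCTTGTCCGTCCACATTACTCCTGATATACCC
AGCAAGTCTATCTGGAATACAACAAAGTTTGTCTATTGTTTTCGAAGACTTGTCCTTGGCCGCAATCTGA
TCGGATAGACATAAGTTCATGGTTTCCATATCTCGATACAGGGTTACCTCGGATGCACTCGGCGGGGCGG
TTAACACTATATTGGAGCTTGGGCTCGCGCATCAACGAAGTACCCGTACAGGAGTGGATTGACAATACGA
GTAAAACGGTTGTTGGTGTAGCGATCCAAGGTTAAACCGCAGGGTGAGGGTTGCGGTCCTACCAAGGGCT
CAATTCGTAAGCTCAGTGAAGGTAGTGGGTTCGTTAGCTCCTCAGTTGGTTTTCGAATCTTCCGGGCTGG
AGACAATCTCATCAGGTGCGGTTGCTTACCGAGATACAATATAGTAGCTGGTGGCGCGTTTCCAGAAAGA
CCAATGCACCCTGATGTACACCCAGTAGTCAACTAACATAGGCACTTCGGTACATAACGACGTGGCGATT
GTTTAGTGTTATCCCTGACTTCTGGCGGGCGCGGTTCCTTCGCCGCCCACCTAGGGGCCATCCGCTCCTT
GAGTGTGGACACTGCGGGCCTACCCCCAGTCGGGCGTCATTCGGAGGCCC
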