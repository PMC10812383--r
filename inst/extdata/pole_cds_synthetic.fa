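>POLE_CDS_synthetic length=6861 note=synthetic stand-in
ATGGGGACAAGAATACAGCCCCCCAGGTGGTACTTTGTACTATCACTGTTTCGCAGGTAC
ACGTTCATTAATTGCACAGTGCGGTGCGGTTCGCAGTGGACATCTGTGCCAGCGCCTGCA
ACCATCCGGCAGTACTTTTTATTGCCTCTGTCCCTTCCTGTGGGACGCGATTGCGGGGAA
CTGGCCTCAGATCAGCGGCTCAATTGGGCAAAAGGTTGCGGCCTTGAGAATGTGCTAGCG
AAGCTTATGACATATACCGAGGGTGGAGTTTCTGGCTCATTGGTGGGCGATTGCGGGATC
GTACCTTGGCGAGTTAATGTGATCGGTGTGCTAAACACAGTTAGAGTTAGGTTTGCAATG
ACGCCTCCTCCCGCTAGGACACGGGTCATTAGGTACAGCAGTTCCAATCCGGACATAGCG
AACGAGTCGATTGTTGCGGCGCCCCAGCAGTCTCAGCACCTATGGCGGAACTCGCCCTGG
GACGATCCTCTTAATTGTAAAGAGGAGAGTCTAGTGTCCTCCTCTCTGAGTAAGTCCACG
ATAAATCTGAGCAATAAGGTTGGGAGGACACCTCTAAAGTGTAAGCAACGGCGAGGGCCC
GGTACTGTCGTAAGGACAGAAGCCGACCACACGCTCCACTGCTGGCTGTATCACCCACAG
AATTTGTCATTGTCTGCCACTAGTACAGCTAAGGGCGTTAATATCAAGTGTCCCATACGA
GTAAAGCTAGTCTCAACAAAAGGCTCCGGATTAGCTTACTCAGAGAGGCGTCGTAATCTG
TTACACATCGCGAACAAGATTCCCTTTCGCCTGGGTATTCTGGATGCCCTTGCGCTCATT
GGTTCAACCTTTTTTCCTCTTGTGTACGGGGCAATTCTGAATATGACTTCTTGGTTCCTG
GATACCCTCATCTACACCCCTCCAACTTGTACCGACAAAGACAAGCGAGTGGTCTCGTTT
ATAGGTAGCTCGGGCCTGATGGGAAATATCCAGATAACACCGACCATATCTAACTACAAG
TCTTCCAGCTATGGAACTCAACGAAATGCACAATCCAAACTACCCCTCGAATTCCAGAGG
GGTAATTTTCGCCTATTCTTTTGTGACGGGATATTAATAAGACACACACTAGCTCTCGAG
GCCCAAGGGAATACGGACCAATTAGGCTTCTTTGTCGCAGGGACTGCGCTAACATCTCAC
TCTCTGACCTTCAAGAGAAAGTGCTGTTACGTTCCTAACGTCAAACAGATCCTTCTGATG
ATCCTGAATCTTACCGAGGTACGCTGTCTATCAGTGATAGATATTCCTCACGCTCCCTAC
ACATTTGAGATGCGGGATTGCCTCGGGGCCTGCCGCATAAGAGGGGCTGGAGTATCTCAG
TCTATACGTTGCGCTTCACCCGGCTTCAAGCATCAAGATCGCATGCACGTCACTACAGCA
GCGTATAGGTACGTGTCTTCGGGTTTTTGTGAACAACCACGACGCTATAAATGCCCGCTT
AGTAAAAGGCTAGTGCTACAACATATCGGCGCGTACTCGACCGAGGAACTGCCAAATCCA
GGCGCTGCTAGAAAGACAACTGTAGCTGTGAGTGTATGTATCCTATTTGGTACAGCGTCG
GGAACTCAAATTTTCTCACGTTCTTCTAACGAACGTGGACAAACCGAGCAGCATTCACGC
AACCGGTTTACTCGTAGATTTGTACTCATTCAACGACCGGGTCGTGATTCCCATAGCGCA
GCTAGTATCGTGCCTTCGTGCCCATTACCCTTCTCTAATAGCATGACCAGCGTCGTGACA
CATTTCAGAGCTTACGATGGCGTCTGTTCGGACCTCCCGCAATATGTTAACATACTGTGC
ATATTTTTCGCCCACATGCGCCGACCGGGTGCGGGTCTCAACAAGAGAATGAATTTGGGG
ATGCTACAAGGATGTGAACCAGATGCAACCCCCGTTCAATTATATCTTGCCCGCCAAACT
CTATGTTCATCTGGGCGCCCACCTTCGTTCCGCCGCCGAACCCGTAACACGGACTCACGT
ACTAAGGATGTCTTAGTTTACCTGAATAGACCTACTTCCGTCTCCTTAGGGAGGACTTCC
GCCCGGCTTATTAAGCCGCCATGGTATCCCCAGATGAACTCATATTGTTGGCCGACAACT
GCCGCGCCCCCGTCGGGAAGATTGAACTCGGAGTGGTCGTCCTTGCGTTGCGCATACTAC
ATGGAATTGTGTATACTGCTCTGTTGTAGACCAGCTAGCTCTACTCGGCGCCACTGTCTA
AGAACCGGTGGTACGTACCAACTGCAGCGTACTAGCCGCGCTTTACCTTATCGATGTAAT
GTCGAGGTGGCGTTCAGTTACGGGAATCACCACTTCGACACCGGGGTTGCTGTTTCACAC
CTGTTGGCTCAACTAACCGACGGCGTAGAGGTAGAGCTCCCAATAAGTAGGCCCCCCAGA
GCCCCGTACTTGATACCACAAGCTGAGGTAGGTGAGTGGGGTATATTGGCCGAGAAAGGA
CACCTCCAGGGGTTAGCTGTTCTCTCTAGGCATGTGGTCTATGGATGGAGTTCCGTCCCT
AAGCACAAGTTTCCAATAGGTCGAATTCCTGTTTGCAATACTCTGACAGAGGTACCCTGC
TCGCGTAACCTAAAACGCGATGATGGAATGCGACATGTCGGTGAATTGCTGCGTCTCGGG
TGCCCTGCTTGGAGATGTCGGAGGCCAGTATCTCTAGTGGAGAAAGACTGGTCCTTTGCG
CTAACAGGTTGGGGTAGCCCGAGTAGCATGACTTTAGCAAGTAATTCACTAGCAACTGGC
GTCGAACGAGTCGGAAAGCTTCATGACAGTATTACTCGGGGAATTAAAGTTGTTTATTCG
ACCCTTACCCCGTTGTTAGGGGGAGTACCCAATGGCGCTATACCGGTCTCGTTGACCGGC
TACCCAATAACCTCGAGAAAACGTTTGGGAACTGAGCTACGAACCTCGAATAACGTCATG
GTTGTCAGTGACCCAACTATCACTTTAGCGCGAATCCGCAGCAATCCCGACTGGTATGGT
CCTAGAGGGGACGTTAGTCGTGATTGCGCTAGACCCTACGCAGTAGGTGAGAATTTATCC
ACTATTTTCCGTAATCCATGCACACTCAGAGTAATTACTCGGAGTGAGTTTACAAAGAGC
CAACCAAGATCAAGTAAATTGTCGGATTTCAATGGCTTGTTTAAGGGTCATGTGCTTTGG
AGCTGGCGAACGAAGGAGTACCCTGCGACTGGACCCCCGAGCCATGACCAGTCCAAGATG
GCGCATGTAAAACGGACTAGAATTACGATTTGTGCGTTCTCGCCCGTCCGGATAACTCCA
AAATCGGCAGCCCGTTCGGAGTCTGAATCTTTGGCGCCAACCTTTTATATCAGGAGAGCC
TCGCGTGCAACATGCAAGTTTGATTATAAAATAGGCTTCCCAATCCCGCTCTATCTTAGC
TTCCTGTCGATGCGTACGATGCTCGACTTACTTGAACTTCGCTGGCGTGCAGTACTGCCA
TGGGGAGCGACCTGCAATTTTGTACAACGAAATAAGACGTACGTCCTTGTACGTAATCTC
TCGGGCCCCTCAGGGAGCGTCCATTTGGGGAGAACGAGGGGTCTGCGATATTGGCAAAAC
GGGCCAAGATGTCTTATCATTGTGGATACCTACGATTGTTGTAGTGAGCGTCAAACTACC
TCCCCCTCGGGAACCCTAACGGGAGCAAAGGCAACTGATTATCGATCGGGTGCGAAGCAC
AAGTACCCAGGCGTGCAGGTCCGTATGGCGCGATACGCCTCGCTCATTAACTTTATCCAC
ACGTGGTGTAAGAAGACTCCACCATTAGCACCGTGGAAAGGTATCATTTGTCAGGTATCG
CTTATGGCGGTCCAGGGGCGAAGTGTTCTGGTCGTAAAGCCCGGTGCGGTCAGTACACAC
AAAAATAAGCACCTAGATATCGTGATTTCTAAGATACCCTCAATCCTCGCGGTAGAAAGC
CACGGAGTATGCCTGACTCACGGAACGATCGTGATGACTGGGTGTCGGATTTGTCCGCAG
TTACTGAACGGTCGCGGGTTCTACCAGCCGTATAGAGTGCTACGCGAATTAGGATGGTTT
TGTACCTTTTGGGCTCGTGGTGTATGTAATTCGGAATGGCATCCTTCGCTTAGATGTATA
GGTCATGACCATTCCGGCCCATACATCGTGTCCAATGCCAAGTACGGAGAACAAAGTTTG
ACCCGGAAGCCGTACACGCATTGTGTTAACGTAGGTAGGGCCGAAACACAAGGCTATCGA
AAGGGCAGCGCCCAACGTTGGATTACCAGCACTGAGCTAGGCTTGTCTGTAACATTTTTA
GGATCAATCGCAGCTCCCGATAAAGCTCTTCTCTCGAGGGCCCAACCTCCAGGGATCGAC
CTGAAGGTCCCCCGCGTTATAATTAAAGACTGGCCACCGCAGATAAAATGGAGGAAATCT
TGCCCCTACCACCACTTACAACGATTGTGTTTCACTCCACGTGTGGGTTACAATTTGTCA
AGCAGCCGGAACAGAAATGCGCGAGTACGATGTGATGCTCCGCCGATGGCATCCCGTATC
ACAATGTCGCTCTGTCCACCTAGCCTGCTAAAGTTACTAGATCTCCCCTTCCGGCTGTCC
AGTAGGAGTTGTCCTAACATTATAGTCGACTCTAGTGCGCATCGCATACCATTCGCTGAG
ATCTTTATTGAGCTAGAAAGTTTGTACCCTTTCGGTCCCCACGGTAGTGCTAGTTTACGA
ACGCTATCGAGTGGTATCACGCAAGATTATTGGAGGATGCGGGGATTTAGTACGGCCAGA
AATATATGCGTTATGCTCAACAAGTCTTGCATGCCACGAGCCCCGCGTTTCTGGCGTGGT
CAACAAGGGTTAAAGGCAGCGGAGGAAATCGAAGGGGTTGGGTGGCCGGATAACCCTTTT
GGTTTTTGGACAGTAGTTCGACTATGTTGTGTTTTTTATAACAGCCTAAGGCAAGTCCTG
AACAGCGGATGGCCCAGGATCCGGGGATGCAACAGCTCTGAAATAGATGGGTTAGCCCTA
ATTGGTAAGGTTGGGTGTGGCTACTGTGGAGAGTACGTTTTCCGAGCCATAACCATAACC
CAGTTTCGCGCGGCACTAATGTCTCAATCGCACAACGGATCGACCCGTTGGTTGGTAAGG
AGCTCAAAAGCGAGACCCCCACATATACCCAGGTGCTCAAAAGAAGCTTCCACTCGCAGT
AACCAACAGGAACATATCATGACTAAATTATGGGTCAGGGTGATACATAATAGTTCACGG
AAATTTGACTACCAATTGGGTCCAGGTGTTCGCCTTTGCATTCGCATCCGATCACCAATG
ACCCGTATCCGATTGTGCCCACCATTCTTCGAATCCAATGCTCGATTCACTCTGCTTACA
GCCAATTCGTCCACCTGGTCAAGTCTGGCCGGATCGGGGGTGGACGGCTCTCTATCATCT
ATGCTTTATCCGCTTAGTCTACCAATCCCATATGTAGCTGTAAGGCACGCAGCTACCGAC
CTTTTATTAGCCTTTTCTGCTAGGACGGCCAACCTTAGATCTTCAAACGTGAGGGATGAC
AGAGCCGTCCGCGTTCACAGTCGTTATGGAAGAGGATACGTACACAAGCTCAGGCGACGG
TTCGTCACTGCAGTTGCCGTTAGCAGTGAGTTCTTCTCAGGGCAGGAGAGCCTACAGGGT
CAGACCAGCCGTGTGGGGGAGGGGCCGTCTACCACGCTGGCGCTACGGGTTGTGGTAATT
ACTATTATCCTGGGTATGTGTGTGTATCACAACATAAACCAACTGGTGTGCCGAGTTCAA
GTTTGGTGCAAGTCCGTCAACGTCAGTTTCCCGTCTGGAATAAAGGGCATCTACATGAGC
CCACATGTAGTTAGACTGGACCCGAGGTTACACCAAAACCGCCGGCACAAGTTTGCAACT
TACTACTGCAGAAGCGTCTGCGACAAACACGTTATTCTCCTATATTCGCGTTACGAACTT
AGACGCGGCGCCCACAACAAGTCCGTAGCAAGATTGCCCGCGTTCCGATGCGTGAATGGG
AACCACAATAGCCTGGGCCTGATCTTGATCATGGATTCAAGCCACATCGTGAAGGTTAGT
CACACGGTCACTTGGCGTGTTCGATACTCTCCTAAAGCCCTCCCGCCCTGCTCTCCAATC
TACGGCGAACGTCCGCTGGCAAGTTTGTTTATCCACCCTAGATGCGGCCGAACAAGCCGA
GATCCAACGTCCCAGAAGAGTGACCTAATGCAAAGCGCAGTGTCCACCGAGTCACAATGG
GCACCGGGACCAGCTAGAAATCCTCCAGTTAATACTAGCCGCCTTCCTAGTGCAATTACG
AAGGCATCCGGTTCGCCACCTCATCGTTGGGTGATGAGGGATTCGGAAAAGGTGACGGAT
GGGCTCGAGGGCACCTCTGGCGCATGTGAATCTCACATCAGTAGACATCCGGGGGGTAAA
ATGAACAGTGGGCGAAGGCATACGTCTCTTATTAAGTTTATTTCCTTCCTTCAATCGTTG
GCCAATGTCCCGGCTAACCCACTTCGGGACTCAGCGTTACCCCTTCACAGGACAAACAAG
CACTTAGCGATTAGGGGGAATCGGCAACCGACGATTTGGGTGCGTTCTCCTCGCCACCAA
ATCACGTTCTCTTCCTCTGTGTGTGGTTGTCGAAGCCGCGTGCGGGGTCGTCGGCCTGTG
GTACATAAGTCAACCGACCGATCTGGGCAGAGAGCAACGCATGTGGGCGTATTAGCAAGA
CGATCCCGGCGGTCCGTTTAA
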