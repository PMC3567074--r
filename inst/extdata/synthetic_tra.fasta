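>synth_tra_seed42
ATGCTTGAGGTGCATCCATTCACCATTCTCGGTGACAACTTTACTCCTCTTTTGAGGAATGCGTCAACGAAAATAGATTA
TATTGTAAAAGAACCGTTGTTAATCCGGTATCGTTTATTCTTTTGTCCAGCTTCCTGTGTAATGGGACAAGAGTGGAAAG
CTTATATAAAGTTTTATTGGCCAAGGCGAAAGAAAATGGTAATTTTCTGTAGAATTACTGATATAGACCATTATAATACT
TGTCAATATTAACAAAAATATTTAGCAGGATTAATGATGATGATCTCCGAAACATAAGCAGTGATCTCGTGCAAACGATT
TTTTAGGAATATCTATATTCCGGCTAAGCCATCATATTCCCGAATAGTTATGTAGTATTAGTTTGGGTGAGACAAGATTT
TAAATGATATGTACAACGAGCAATATACAGTTATGAGTTAAACAAGACATAATTACCCAAATTCTAATCAATCAACATAC
CAGTTAAACAATGCATTTATCAGCAAAAGGTAAGTGACAGTATTACTAGTATTGTGCTTCGAAGGACGCTTTTTTATAGG
ATTAATTACTGAAATTACACGTCTTCATTTTAAATGTAGCCAATCTCTATAGGTTTCTGTACGAACTTTGACCGTAGCCA
TGTATACAGTACCTACTGAAGCTTTTACTGCACGGAGGGTAGATATCGGGATTCTCTAGATGGAGTTGTAAAGGTATAAA
GGATTGTGCTAACGCCTAGATTTATGTATCCTGGCCTTACCTGAATTGAGTTCAAGTAGAAGAATTATGATCTAACAAGA
TTATATCACAAGAATATACATATTATTTAGAAATGATATAAATGATCTTCGTCAAGCACCGTGACAATACTTTTCTCCTG
TACAAAATGTATTAATAGATCATCTTGACCTATACATGAATTGTGAAACACTGTAATTAGACATATCGTTGTATGGGTCA
GACAATGCGAATCAGGGTCTTTGATTTTCGAAGACGTACAATGTACATATAGTTATTAGAAATTAATGGGATGTCATTTT
CGGCGGCACCACGTAAAAATAGGAACCAGTATAACTAGAACAGTTTCTCGGTAGTATAATATACAACGGAAATTATGATA
CACCAGAAAGTTTAAGGTGGCTACAAGTGTATTTGTATTCAGAACCATAAATATTTAAGATCACAATAACACCATACCTT
GTATTCTTACATTGTATTGCGTACACACTTCTTTACGATTTTTTAACTGTTCAGACGAGTATGTGACCGACATGGGCCTA
CTGACGTTCGTGGAGTCAGGTCAAAAAAGAACGTAACGGAATTCATACCCTACATACGAGTCACCCTCCTTACACGACAC
GATATCTATAAGACACTGGGCGATGAAGATTCAAGATCATACTGTCGGAAATACGCGGCAGCAAATCCTGCCGTCATAAT
GAGAGGCTTTAGGATGCAAAAAATATACATGCGCAATGGAGGGAGATTATTTCTAACTGCTTTACATAAAGAAAAGAGTT
TAGAAGTTTGTTAGCGTGCGCCGAACTTTTCTCTAATTATGAGGCAACTTAAGTCTAGGTAAGAAACGCTGATAGTAAAT
TAAAACTACTCAGAATCTTCCTATTCTAGAAAGTAGTGTTTAACAGTATGAGACTTTACGGACGTCCAACACAAATTAAA
GGTAGTTTCTTTGCATGATGATTTTGGAGCGGCCCATATAAACCATTTCCTGGGCCCTCCCTAATACGGAGTCCGTCTAA
TAAAAGTGCTATGTCTATGGACCAGCTGTAATAAAACATATTATTAAGGGGGCGTTGCAAGATTCGCAATGTCTAGGGTA
TCGGCAAATGGTACCTATCCTAAGCTTGCGTTACTAAAGTTTAGGGTATTTGTCATGCGTCTATAAGGCAATAATAACGC
CCATATGACTTCTTTACTGCTATTTGACAAACTTTATAATTTTTCCATATTAAACACTGTACTTTGGTAATTGTGATTAC
GATCATACGATTTTCTCGGTACTTAGCAAAACTGATGTTGCTGTAAACTGAGTATTATAACGCCCAGTTCTAAGGTATAA
CCCATCCCAACATGAATATTATTGTACTCGGAGAAGCTAATAATGAATTTTGGAAGGGTAATCATGTAACCCTCATCAAT
CAACAATTATTAGTATGTATTGAAGATTTTATACGCCAGAAATATATTTTAGGTAGAATATGTGAAAGCAGTATATACTA
CTACTCTACAATCAACACTTTTTTCGTGATGACTAACTGTGTAACTGATTCGGTTGCGGTTCACGAAGAGACAATCAAAT
TTGTTGGTAATCCTAGTACATACACGAAGAATATTCAATCAACAATACTAAATTACACTAATTTTCAGGAATTAATTGCA
GAACGACGTTCGGCTCCCATTTCAGAGACACAACAATCAACAATACTATCAGAGGAATTCTACCTAAAGCTGCTGCATTG
ATAAGGAACATTACATAGGGATTGATGAGTTAAAATCTCTTCCAAAGGATATTTGAAAAGCTCATGAGTTGTACAGCCCT
ACATTGTTTAACGCGTTCTTAGTAGTAATATCATCTTATCAACATACCAGGATTTGATAATAACAACTACAGATAGGCAT
TATCCCGAAGGTAGAGCTTGAAGAAGTTCTTATAATTAGTGTTTTCTTTTTTTTTCAGGTGAAGGTTCAATTTATCTTTC
TATCAGAAAATAAACGACTTATAATTAATCTAATAGATTTGAACTACACCAGTACTATTTTAACTATATACGATTATTAC
TTATCCTACAACTACCAGCCTTACTCTCGGCAATGTTACATAGTAACTGTAAGTGTGTTTTGCTCTCCTGACGGTACTAA
TTCTACTGTCTCAATTCTAACCGAATATTTTTCTTTTCAGGCTTACGTGCTTTGTCTTTCTAAAGAGCAAACTTTATGTC
AACTGAGTCCTAATTTCACAATATACAAAGTAATCGTATTGTTTTACATAATGCTCATAGGATTGGTAAGCCTACAATAC
TCTACCTTTCAGATCACTCAAACTCTTAGAAAAATGACTACAGTAAGTTTCGCTTCTACTCGATCCTAATCCTACCCACA
TCTCAAAAGATCGCGATATCAGTAATTTCAGAGAATTAATTGCCATGACTACAGTTATTTAGCTATGGATACAGAAACAC
GGAAAATGATGTACAATAATTACGTATCCTGTCTCGTTTATTACATTGATTTTGTCCAATATTACAGATGTTATATGATC
GAATCTGTTCCACCGTTAATAGCTGAGTTCATGATAAAAATTCGCTGTAGTTACCAGTCCTGTAGGGAATTCCTGGGTAA
GATATACTTTTTCCCATTGTCCTTCCTAGCTAATTAA
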