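>16S_rRNA synthetic template
AAGTTTTCCTGGGCAAAGGGTCGTGGCATGGTTAGATCGCAGGGATCATAGACCAGTCTTAAGCTGTGTAAATGGCCTTCGGACCTAAGATAAACGGTCCATCCTCTATGCGCTCGACACAAGCGATGGCACGATTCGCTTCCGTCTCGCCACGCGCCAACATTGCCTGCGATTTGGCCACGGACTGGCCTCATCCTGAGCCTGAACGGAAGCTCCCCCCAGTTGACTGGTATGCATCGCCTTAGAGGGGGCGCCCCAGGTTCGAAAAGACCTTCTGTCGTATGAAATTCTATAAGTTATATTCTCAATTTGTCGAGCTCCCCCTCTACCTTGTGTGCTACAGCACGTCCCACTGCCTACTGCGGCTGGGTCTTGGCTGCAGGAGCAACCAGAGGGGGGACAGAGGTTGCAATGGAAACTGGAACAGAGCTAGGTTCGGACGAGAAGCCCCGGCGTGCATTTTCATATACGGGTACCACGTTGATGGGAGCTACGAGTGCGAAGTCAGTGTCGAACGACTCCCTATTTGCCGCACGAATCGGAGCAGCCGCTAAGTGCTTTCTGTTGCATGACCCCCTCACAATACGTATTGTTAAGCTCCGCATCGCCGACCCGCCGTAGCTTGTTACTCCTGTACGTGATACTGTGCGGGGGGGGATGGCGATTCTCGCCTACATTTAGGGACCAAGGACTCTGGCGGAGCTACGGCCTACTGCCTATGGGCCATTGTCTCCGGCTTATCCGCGTCTTATCCTCTATACTCGGATGAGTGGGTTCACGGTACAGGGTATGTACCATCGAGCACCAATGGTAGGTTCTTTATCAGACTGTTCCTCACTATAAAAAGGTCCTATGAACGGGGCCCCGGAGGTCCCGTTACGAGCCGGTACTCAGTTAACAGTTCCGGACCAGTGTACCACGCAGTGTGGACACCCGTCCACCAGTACACAATCGTTGAAAATGCGCCGCGTTGAGGGGGACCGAGAGCTTCCGAGCTTTTCAAAGCCGGATGTTGTTGTCGGGACTGCTAAAGTAAGTTCCCACGAATGTACCCCCATGAATATGGGGCACAGTTACCGCGTGCATTATCTAGCTTGAACGATGGCAGCTCTTGCTTGACTCTTTCGGAGGTCGAACTGAAGGGCTACTGGAAAACGTGGGGGATAAGCACGCATCGGTCGAATCGGAAGCTAATGGGGGCGGCACCAAACCATTTTAACGGACAGGTCGCTATTCTACGATGCGCACGCGATTGGCCTGGACGTGCGTGGCGCGCGGACAGGGAATTGAGGTTTACCCATCAAGTTAACGAGACGTTGTGGGCTGCCGGTTAGAACTGTAATAGTTCAACACGCAAGACGTTTATAGTAACAATACAAGACTCCTTGTCGATCCCGACGTAGCACCTTCGCGGACACACCATAACTCACGGAGCATTCACATGAGTCACGTGGTGACTGCTATATTTTAGGCTTGTGTCGCTTGCAACTTTGCGAACATGGGCGGCTAGGC
>23S_rRNA synthetic template
CGTTCGGGTGACTTCTAAAAATAACCAGCGAATCACCCCCCAGTGACCGCGGAGCAGCTGGTTGTCATGCCGAAGAACGCAAGCCCCCACAGCTCTTAAAACCCATATCAGCCCGACCCCAGGGTTTAGTCGTGTTACGCCTCCCATGCGAGCTATGGCTGTCCATCCGTGCGGGCGTTTAATTTTAATGGACTCCCTCTTTAGGGGGGGTGTGTCAGTAGGCTGGTGCAAGTTTTCCGACCGTTATGCACTAGGGGACAAGCTGACTCGGCTTTAAGGGGCGAAGTACACTCCGCGGTTTTAAGTACAGGGACCGAGACTAGACTCGCGAAAAAAGTCCTGCCAAGCTGAGGTCCTTGGAGATAGAATGCTTATCGGGTTGAAGGTGGGACAGATATGATACCATACTTCTTTCCAAGTTATGCGGAGGGATTCATACTCAGAGCGATGGGGTTTGGTGAGCTCACTAACATTCTTGACATCCCTATGAGAGCTAACTGACAAAGACGACGTAGCTGAAAGACTAAATAGTTCAACGTTCTTATAAGCTGCGTGCATTCCCCAGGCGTTGGCAGTTCCACCCACACTGGGAATCGGGTTCTAGGAGTAAGGCTGTATGGGCGAGTCCACGGTTAAATGTTCATTAGGCCGTGTCCTCTCTAAGAAGCATAGTTCCGTACGGGCCGTGTTTACCTACCAGGGCAACTCAAATCACGATCACGCAGGCCACCGTAACGCACACGTAGGCAAGGAAATCGGAGGGTATGGAGCTGTAGTCTAGGACCTTTACACGCCCCCCTGCGACAGACACTGACAGTTCTTCCTGCGGGAGCCTATGTTACGCTGGCATATGTACCGATCATGGTAGATTCTATCTTATGCCTCAGAAGAAGGTGCCTTAGGAGCTCTGGCCGTCGTGTACCCGCAGGGTGCAGACCCGGCTAAAGACAAAACTAAGCTCACTGAGTCCTTGTGCTCGTGGGGTTCTGGTCAATCCCGGCTATCGGACGGTCTACGTGCGCGCAATATGACCAGGCTCGCATCAGGAAATATGTCTGCGCTTGCTTCTGATGTGTCGGCATCTGCACTGTCGCTGTGCTCGACAACTGACGAGGGCCTTCAGCGCTCGGCCACTTTGCTGCATAGTGTGGTGGTGTGGCTAATGAGCGTAATTTGAATCCGTCAATTCTAGGTCTGTCAAACTTTTACAAGCGAGCCGACCGAGGGAAAGCAGTGACGATACGTGGCGCTGCAGGAGATAGTAGTGAGTGATAGGTCCCGCCATACGTCAACGCATCGTGGTTTTAATCCTCCCTACCTGGCACGGTTGTATCTACTCCCTGGCTAGATGGAGAGGGCAAGTGTACCGTCCTCAGCCCCCTACGCTCCACGACTCAGCTACTCTGTTGACATCGACAAACAACCGTGTACAGAGTTGTGCCATTAGGGCCATTCATGATGGAGCAGCTGACTCCCCCAAATTCTGCGGCCGAAAATCGCTGTTCGACGCGTGTTTTGGAGCCCAGTAGTTGGATCCATCCCGATTGGCGTGGCCGGGTGCTCAGCTTAAGCGCCAGGAGTTCGACAGTTGCTTGAAAATTCGCATCAGCGCTTGCCTCAGCTTGCCGTCTCGCGAGACTTGGCCAAAGCGGCATTTCCCTTTCATTACAAACGGCCATTGAAGCTATGACAAATGATGCTACAGTGAGAGAGCCACAGCACTGATCAGATCCCGCGGCTCTTCACGATCTATCGGAGCCACTTAGGAGGCGTACTCTTGGACGCATTACACTCCGTTCCACCGAGACATTTTGGTAAATCCTTGATGGGTGGGCTGCCCCTAGACACGGCCACCTCTCCAACCATATAGTGGGGGCGCCAGAGTGCTGGCGGACAAAGCGTTGCCCGCATCGAGCTGTAACGCAGGATCCCCAACTAGTAGTTTCTCATCCCTTTTAGTTGCCACATGCCTTTGCAAAAGGGGATCACAATCGATCGTAGGGCCCCACGAACTAACCGGGATTAACCCCGCCCATCTGGCGCCTATGTGGGGCGACGGCAGGGACCGTTGTACGTATGCCATTTGGCATTGGTTGGAGGTCAGTTTCACCGATCGTTGCCAGCGACTCTGCCTGGTTTATGAGGGGCGGACAGTGAGGACGGACCAATTACGGCTGCCATGGTGCACCGGCGCAGCGTCCGTTGTAGCCGCCCTTGAGACATGCGTCGTCGAATGCTAAGGAGATGAGATCAGCTGTGAGTATATATACCTTGGTCTCTTCTTATGGTCATCGGTTCCCATTGTCCTCCAGTTTAGACGCGGAGCAGTACATCCACCCCCTCTCTGGTTATCAACGGTCTACCATACTGGACCAGATCTGCCGACACAATAGAACTCTTGATCCCGTGATGCGTCTGTACTTAACTCGGTCAAGGATTAGAGTTATGCAGGACGTGCATAGTTTTAACTTAAAGCACGTGCCGCTTTGACGGTTACACTTCTATTCTAAGTGGGGCTTTGTTGGTAAGCCCTCCGGAACGTTCTTGCCTTTATTTGCGGCGGGGATCTGTCTACAGCAGTTAGCCCAAAGTGGCGATACATATTCTGATCTCTCGAACGAACTTGCGATGACGGCTGCCATCCACTAGTAGAGACGTGCATAGACAGCAAAACTGCACAAGCAATGGAACAGCCCCTTGAATCGGAAGTTTTAGATCACAAACCATCGCACGCTTTATGAGCGTGGCCGGATCCCGTTTTGGCACATGCTAGCGTAAGTGCGAAGTACTTCTACGCATTGTCCCGTTCCCGTACCGCGTCGATGGGGTCGCATGTCAAACGAAAGGAAAGTCGCCGCATAGACCCACTGCATGTTCGGTCGAGGGAATCGAGCCGGAAC
>5S_rRNA synthetic template
GAACAACAGAACTGACACAGCTTGCGTATTGTTACCAAGTCAATTGGCTATACGAAAACATATGCACTGGCCGACGTATATTTGGTAGCGGATAAACGGCCGGTGCGGATATAAT
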