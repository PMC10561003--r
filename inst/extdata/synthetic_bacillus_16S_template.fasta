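>synthetic_Bsubtilis_16S tax=g:Bacillus,s:Bacillus subtilis (synthetic stand-in)
CCCTCGGATTCCAGACGGCAGATAAACGACTGGAACCTTTCGGGGGAAGAGTACTTCCCTGTGACCGGTT
TAAGTCTTTGCCTAATTTAGCCAAGGACAATCGGTGCGCACTTTCTGATGGACCTCCGGCTCCTAACACT
AGAATAAGTATGCGCTCCACACCTGAAGGGACGCGGGTACTACTGTACTTTCTTCTAGGGTGTTTTCGGT
CCGGCTGAAGTATGGCTCGCGACGTGGATCTAAAGACAATAGACCGATCTTTAAGGTGCTTCCGTTAGCC
TAGTAGGGGCTGGTGAAGGGGTCTGTAACTGACGCTGAGGCAGCAAACTTTTCACTGTACAGTGCTAGTG
TTAAATGCATCGTGAATAATTTCGGTAGCACCTCCAGTCCTGTACACAACACCAGGACTCTCACGCGAGG
CTTGAAGACCGTCCAGCGATTTGAACCCAGATATAAGTCACTCATTCTAATGAGGCCGAGATCGCCATAG
TGAGTGTCAAATGCATGGTTCGTCGGTCGGTACGCTGAGCTATTAGACACTTAAAGAAAATATAGAAAAG
CGTGCTTAGGCTAGTATAGCACTGGGAACTTAAATGTGGCACACCTCGTGATTGTCAAGTGGCCCATCCG
CCCCGCAGCGGGCCTTATAATCATGTTATGTCCTTAAATTCGGACGGCGCGGTACAGCTAGGAGTTGACC
CTCTAAGTTAGACCCCTCAAACAGGGGAAGCTGAGTGAAAAATAACTTAGACGACAGAACGCCTCGTCTT
GTAGTCGAGGCGTCATCCGATAACGCCTGACATAGGAACCGTTAAGCTTATCCGGGCCAATAACTGTTTA
ATCGAGATAAGCCCCAGGTTAGGTCTCAAGGATCTTTACATGAACTATACCTTTCTTGGAAGCTGGTTGG
AATCGCTAGTAATCGCTCTCTCACAACCAGTCACTGGTTTGGTAAATACACCCCGCTGACATACTACTTC
CTGGGCGCCGTTCTATTCCTTTGGTAGGCTGTAACACGTTATCTATTGCCGGACTGACCGATCTCGTCTC
GTACCACATGCCTCAGTACCCACGCTTCCAACTGTATGGATTATATGTGATAGACGAGTTACAGGTCACG
ACGGATGGGTAAGCGGTGGATAAAGTAAGGGAGTTATCGTCACTAGAGAAGGTTCGGCATGAGCGGCCCC
AATTTGAATTCACGGCGCCCAAGGGGGGTAACAAGCGCCTGGAGGTTTTCCCGGGGCCGTAGTAGAGGTA
TGCACTCCTGAAACGTACAGTCTAGACATTCAACTCTGATGGTGGACCTCCTAATCTTGTGCCTCGTGTG
GAATATCAGCCAAACGTATTCACCGCGGTATCACGCGGCGTGGCAAATCGTTCACAGGCGTAAATTCACT
GCATAAATTGGTCGGTACGTAAGGCTCAGCATAAAGTGGATTGGAGGTTGTACCTATTTGTTGTGACACT
CGAGCACTTACCCATTACCCTTGGGCTTGGCACCGCATTGCTGGTGTTGCTGTCGTATAGTAAATTGATG
GTGGCAACCC
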