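>synthetic_Abaumannii_16S tax=g:Acinetobacter,s:Acinetobacter baumannii (synthetic stand-in)
AAACATTTCGCTTGAAGTGTGGGAGCAGATTGTGTGACCTAGGTATTAGGGCTCAAGTCGGTCAATCTCT
GGCGGGTGACGCTAAGCGCACGGTGGCTCTTCAGACCCGGGGCCATTAAAAACGAATGATGGCCACTTAA
CAACGCACACCTACCTAACCTCACCATTCGAGCCACCCTTCAGTCTTAAGCCCCTGACGACTTTTGGACC
GAAGCCGGAGTGTAGTTTGGGAAGGGGTGCTTACCGAGGATGTTTCGAATAGACCGCGGCCCTTTAACAA
TAGCATGATTGCCATAACCCTGCAAGTCCCCAAGGGGACTTTCAAGAACTAGAGGCGGCTCCGAGCATTG
ATGTGAAATCCCCGAGCTTCGTCTGTGGACGCGTCCAAGGTGAGGCAACCTTCATTTATTAGTCAGTTTG
TTCCGTAGCCGAATACACCATCCGCCGACATCGGATCCCGATTTTTAGGGCGTTAGCACTTTTAAGATGC
ACGGACGTCAACGACCCGATATCAGATATTCTGTCCCGTAATAGCACCGCGGAGGTGCGCCGCAAGTTAA
CAAGTCTGTTTTGATCCGGGGCATCCAAAGAGGAATGCTACCGTTTCATGCCGGTAGTACCATTTAATAG
AAGGGCAGAGAAAGACAGTCTGGTTTCAATCCTAGACGTGACCTTCACCGTAGCGAGATGCGCCGAAAGA
ATCTAAGCATACACCAGTAGGGACTGCGGCAAACTTACTCGGGACCCGGTACGATATTCGCCTATCAACT
TTAGAACTGTTGACTATAGCGTCTCATTTTTTGGGGCTTCACTGCAGGGGCGCCCAATGAACTGAGTTCC
TATGATCTATACATGCGATATCTGAGGATACTGCCAGTGACAAACTTCAGGCTCTCCGGCAGGGGAAGTT
GGGCGCCGAGTGATTATTGAAATCGGAATGCGCCGCGTGCTCAAATGCAACCCTCCGAATGCATTTGGGA
AAGGGAGATTTTACTTCATACACGGTCTGCGAATGGTCTGGTAATTGGTCAATACGTGACCTACGAGGTG
CGCGGAGATTACGCTAGGGCCTAGACCCTTGCCATAATAAATTTACTGTCGTTGTACTCAATCTAATAAC
CCATTAAATGATTAGGGTGGTTAGGCCTTGCTCCGTATTGGCACTTGTAATACACTCTGTGGGGGCCATC
ACCCCCATTCATCTTACTTAAGGGATCGGTTCGATTCTAAGAACGGACTAACCTCATGAAACGTCGACCG
TGACGCTTATCTCCTGGACCCTGGTCACATCTACCACTGCATTTTCGCATTCCGTAACCAGACGAAGTAC
TGAACTCGATACTGTGTTGTGGGTAATCTGACTAAAGCGTGCTGAACAGTGGACTCCACTCTGTAGGTTT
CCTCACAGCGAGCAGAGATGCTCCACATTCGGTAAGCATACGGAACACCCTCCTGCGAAAGAAATCTTGC
CCCGGGAGGAGCCAAGCGGTCACCATATATACAACTCCTTCGACAACCGTAAGAGATTTCCCACAGATTG
CCTAGTGCAT
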