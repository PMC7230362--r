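>speciesA_synthetic
CCCTCGGATTCCAGACGGCAGATAAACGACTGGAACCTTTCGGGGGAAGAAAAAATCCCTGTGACCGGTTTAAGTCTTTG
CCTAATTTAGCCAAGGACAATCGGTGCGCACTTTCTGATTTTTTTCCGGCTCCTAACACTAGAATAAGTATGCGCTCCAC
ACCTGAAGGGACGCGGGTACTACTGTACTTTCTTCTAGGGGGGGGGCGGTCCGGCTGAAGTATGGCTCGCGACGTGGATC
TAAAGACAATAGACCGATCTTTAAGGTGCTTCCGTTAGCCCCCCAGGGGCTGGTGAAGGGTCCGGCGCGCTGGCTATGAT
CAGCAAACTTTTCACTGTACAGTGCTAGTAAAAAATGCATCGTGAATAATTTCGGTAGCACCTCCAGTCCTGTACACAAC
ACCAGGACTCTCACGCGAGGC
>speciesB_synthetic
CCCTCGGATTTCAGGTAGCGAGCGGACAATTGGAGTCTTTCGGGGAAAGAAAAAGCCCTTGTGACCAGTTTGAGTCTTCG
CTCGGCCTGACCAAGGACGGTTGACGCGTACTTCCTAATTTTCTTCTGACCCCCAATACTGAGATAAGTATACGTTTCAT
GCTTAAAGGGATATGAGTGCTATTACACTCTCTTTCAGAGGGGAGGCGGTCCAACTAGAGCGCGACTCACAGCGTGGATC
CAAAGACGACAGACCAATCCTCAAGGTGCTTCTACTAGCCCCTTAGGAGCTGATGAGGAGTTTAACGCGCTAACTACAAT
TAGCAGACTTCTCACTATATAGTATTAATGAGAAATGTATCGTGAATGGTTTCAATAGCACCTCTAGTTCCGCGCGCGAT
ATTAGGACTCTCACACAAGGC
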