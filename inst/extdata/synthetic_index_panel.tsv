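sample_label	forward_index	reverse_index
sample1	GCGGGCCTTATAATCATGTTATGT	CCTTAAATTCGGACGGCGCGGTAC
sample2	AGCTAGGAGTTGACCCTCTAAGTT	AGACCCCTCAAACAGGGGAAGCTG
sample3	AGTGAAAAATAACTTAGACGACAG	AACGCCTCGTCTTGTAGTCGAGGC
sample4	GTCATCCGATAACGCCTGACATAG	GAACCGTTAAGCTTATCCGGGCCA
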