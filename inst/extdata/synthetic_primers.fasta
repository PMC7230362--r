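>fwd_primer_synthetic
AACTTAAATGTGGCACACCTCGTGA
>rev_primer_synthetic
TTGTCAAGTGGCCCATCCGCCCCGCA
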