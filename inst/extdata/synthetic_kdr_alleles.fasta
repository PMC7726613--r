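>kdr_L1014F resistant=true allele=L1014F
CGGAAAGCATCCACCTTGCTGCGCTAAATGATGTCAAACCTAGAACCTATAGCGTCTGCGCGGATTTACGCAAGAAGCAA
CTCGGTATCATACGGGTCCTACAAGTCAATCTCATGTCCGCTGCGAACTAGCGCTGCATGTTTGTCCCAGAGTCGACGCA
CCTCCGTTCGTAAATTCTTGATTGCCACACTGGCCAAGAATCCCGAGGAGATTCCAGGCCACAGGATATAGTCACGG
>kdr_L1014L resistant=false allele=L1014L
CGGAAAGCATCCACCTTGCTGCGCTAAGTGATGTCAAACCTAGAACCTATAGCGTCTGCGCGGATTTACGCAAGAAGCAA
CTCGGTATCATACGGGTCCTACAAGTCAATCTCATGTCCGCTGCGAACTAGCGCTGCATGTTTGTCCCAGAGTCGACGCA
CCTCCGTTCGTAAATTCTTGATTGCCACACTGGCCAAGAATCCCGAGGAGATTCCAGGCCACAGGATATAGTCACGG
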