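locus	forward	reverse	expected_len
bact16S	CAAGGAACTCGACAAAAACC	ACCTAGGAAATACCGAACGG	270
S200X6.1	TAACAAGTCAAACCTTAGTCGA	CATGGGTTTAAGCGTGTTCCG	258
cox1	GACAACGAGGGTCCCAGGTTTAGTGT	CGTTGGGCCTCCACCCATAGTCATGG	252
kdr	CGGAAAGCATCCACCTTGCTG	CCGTGACTATATCCTGTGGCC	237
mamm16S	GAGATCGCGTTGAACTTCT	GTTGCACAGAGTCGTGGAAC	179
parasite	CCCAGGAGCGTGAACGTCGTGTGCAGT	ACCGCCATTTCGCTTGAAGTGGATA	222
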