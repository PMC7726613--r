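>Anopheles_gambiae taxon=Anopheles_gambiae
GACAACGAGGGTCCCAGGTTTAGTGTCCACCTAATGGGCAGGTAACTAGACTAGAATGCCCTGCGGAACTAGAGCACAGC
CCTCGTCGTATAGGGAGAATTTACTGGATACACCCAGAACCACGATGTGCGAACCTGGCCACTAGCGTTTTGAAATGATA
TATGGCAATTAGACGTATGTGGATTTTATCCCCAATGCCCTGGCCCAGCGCTAATTCGTCCCTGGCCCATGACTATGGGT
GGAGGCCCAACG
>Anopheles_coluzzii taxon=Anopheles_coluzzii
GACAACGAGGGTCCCAGGTTTAGTGTCCACCTAATGGGCAGGTAACTAGACTAGAATGCCCTGCGGAACTAGAGCACAGC
CCTCGTCGTATAGGGAGAATTTACTGGATACACCCAGAACCACGATGTGCGAACCGGGCCACTAGCGTTTTGAAATGATA
TATGGCAATTAGCCGTATGTGGATTTTATCCCCAATGCCCTGGCCCAGCGCTAATTCGTCCCTGGCCCATGACTATGGGT
GGAGGCCCAACG
>Anopheles_melas taxon=Anopheles_melas
GACAACGAGGGTCCCAGGTTTAGTGTCCAGCTATTCTGATAAGAGCGAAATGACCCCTAAGGAGCAGTGGCCATGTCCGC
CCAAACGGGGGGTGAAAGCTTTTAGTGAAAACCTGACCTTCACCCTAATGGTCGGTCTTAATACCTGGGCCCGGCCATGG
TGGAGCAAAAGTCTTATTAGCCTACGGTCGGAGTGTTCCCAGGGCGGGCAGAATTCGGAGCGGTACCCATGACTATGGGT
GGAGGCCCAACG
>Anopheles_arabiensis taxon=Anopheles_arabiensis
GACAACGAGGGTCCCAGGTTTAGTGTACGGACACACGCATAACCCACCAGATCTCGGCGGTTACATTAACCCCTTTCAAG
AATCGCACGCCTACCCCCCGTAAGCGCTGTCTGCGCATTACCAGGCATGCCTCCTGACTCGGCTATTATGGGTTATCTTT
ATAAATAGCTTAATCGTTATCCATTAGATGTAGAGTGAATTCCGGTGTCAGCCAGTACCTGAATAGCCATGACTATGGGT
GGAGGCCCAACG
>Anopheles_nili taxon=Anopheles_nili
GACAACGAGGGTCCCAGGTTTAGTGTTATCTTCTGTCAGATCGATTTTCGTCCGACCGTAGCGCGGAATATGTCTGGAGC
GTTTGGGTTTCCCCAACTCGCTAGATTTCACTTATTCTTAGGCCACACTATCCGTGCCTATCTGCTATGCGCCGCGGTGA
CAATAGGCACCCAGTCGACACGTGCATCTCCATGTTCTAAATCGCTATCTTTCAATTGTACTCCGTCCATGACTATGGGT
GGAGGCCCAACG
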