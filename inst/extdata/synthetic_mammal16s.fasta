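>Homo_sapiens taxon=Homo_sapiens
GAGATCGCGTTGAACTTCTCTTGAACCTACAATTAAGGGTTCGAGACCAATGGGCCCAGATTTTGGTGCTATCGGGTCAC
TTCGGGCGCTCCAGGCTAATAATCGAATATGCTGAGTCCTCCGCAGCGGTGAGAATTGGGAGTGCAGATGCACAGAGCTG
TTCCACGACTCTGTGCAAC
>Bos_indicus taxon=Bos_indicus
GAGATCGCGTTGAACTTCTCTACACAGGTGAGTTCGGTATCTCTGCATTCCAAGACTGTCAATCTGTACGTTGGTCGACT
CGTGGCCGCAGGGGCGATAAACGTCAAGGGTAATATAGCTTAAATTGTAGCCAATATCCACGTTGCTCTGGATCATACTG
TTCCACGACTCTGTGCAAC
>Ovis_aries taxon=Ovis_aries
GAGATCGCGTTGAACTTCTCACTTAGGCAGGCATCTGGGCCCCGAAAAAGTGGGACCCATGACCAACCCACTATGATTTT
GTTCCGAATAGCTTTTTCCGTCAAGCAGAATTATGGTTCGTTACGACGACAGATTCTCCGACGGTCAGCGAAAGAGGCAG
TTCCACGACTCTGTGCAAC
>Capra_hircus taxon=Capra_hircus
GAGATCGCGTTGAACTTCTGTCGCTCACGAGCACGATCCCGGAAGTTCTATAGAGGCGTCTTGTGTTGACCGCACGCCTC
GTAAGCGCTGCCGATATGCCTGACACCGATACAAATACAACTCCTAAGAAGACACCAGTCGATTCGTTTCTTGTCTCCTG
TTCCACGACTCTGTGCAAC
>Canis_familiaris taxon=Canis_familiaris
GAGATCGCGTTGAACTTCTACGAGCCTCGGAGCCTGGGCTATAGGAGGTCTATGGACACTCGCTTAAGTGGCGAGGAATT
TTTGCGCCCTCGACCCCGACTCTTCCACACCACCGATGACGACGAGATTCAGTGCTTTGTCAGTCCTCAGGTCTGAATTG
TTCCACGACTCTGTGCAAC
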