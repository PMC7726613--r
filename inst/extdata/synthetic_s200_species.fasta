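>Anopheles_gambiae taxon=Anopheles_gambiae
TAACAAGTCAAACCTTAGTCGATTATGGCAATGTCTGTGCCGCTTACATTTGATAAGAACAACTGTGCGAACAGGGCGAC
TTGACTTCATTTGAGTGATTCAAATAGGTTGATTGGCATAATTGCCCCAAGCTGCCCACGAATTTCAAAGGAGCGCGCCC
TCGGCCTACCGGTCGTCGTCGGCAAAGCAAGGCCAACCACTAAGAGAAGGATGGAACAGCCAAAAGCTCATTGGTTGCGG
AACACGCTTAAACCCATG
>Anopheles_coluzzii taxon=Anopheles_coluzzii
TAACAAGTCAAACCTTAGTCGACTGTTAGGCGAGTAGTACGCCCGCTTCATCCTTAGCAGAGGTACTCGGCGACTCCTTT
GTATCAATCTGCGCAGTCCTTGTAGCAGGCGAACACGCGTTACGTCCTCCTTCCCCTGATCACCTCGAGCAAATTTTGGA
GCATTGCGACGTTCCAATGCCTTTTTAAAAGCCGCCGCAGAAATGTTCGAACAGAAGAAGGTTATGTTAGGGGCAGCCGG
AACACGCTTAAACCCATG
>Anopheles_melas taxon=Anopheles_melas
TAACAAGTCAAACCTTAGTCGATAACCCCCGTCGACATAGATGGCAGCGGATTAAGTCACAACCGAACATATGAAAACGC
AAACATGAATGTACGGAATGACAACATTCGTACATTAACTCGTATAATACAATAAAGAGCTCTAGCAGGCCTTCTCTGAT
CGTGTAACTGGTCTAACCGCCACCGGCACCTTCAGCGGGTGTGCGGTAAATTATACTAACGACCTTGGTATTATTGGCGG
AACACGCTTAAACCCATG
>Anopheles_arabiensis taxon=Anopheles_arabiensis
TAACAAGTCAAACCTTAGTCGATGTAAGAGTATTATTTGCGACGCACGAACACACAATAAGACCCGGCGCTATTTGACCT
GCCCTAATGGTATTGGTCATTCACAACACGGGCACAAATGTTTCGGCAGCCGAGAAACTTCCCGCACTGGACTTCCTTTT
CGGTATTAGACGAACAGGTACCCCATGAAGTTATTTAAGGACGAGTTTCTAGGTTCAACAAACAAATCTAAACACTCCGG
AACACGCTTAAACCCATG
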