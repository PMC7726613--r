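>Plasmodium_falciparum group=Apicomplexa
CCCAGGAGCGTGAACGTCGTGTGCAGTCACCAGTTACGGAAAGCAGGAAGAAATTTTTTGCATGGTTGGAACCCTGGGCC
TTGTCAGCTGGCTCCGGGTGGGCACATTTCTGAGAGTATTATACGTTATGACAACCTCACACGAGTCAGGGCGCTGATGA
GACAGAAACAGTTCCCTGAACTAGTTGAATCGAACGATATCCACTTCAAGCGAAATGGCGGT
>Theileria_sp group=Apicomplexa
CCCAGGAGCGTGAACGTCGTGTGCAGTGCCGTTTCTGTACTGTATCCCAAAGAGTGAACGTCTTGAACTACAACACCACG
GACGCTGAGTGGGTCAGAAAACACTGCTTTGGTGACCATCCAGTTCGGAGAACGGTGGCGCTGACAAAATAGGCCGATAG
CTGCCCGATGACCCAGGGCGACCTCTAAGAGCACTCCTATCCACTTCAAGCGAAATGGCGGT
>Loa_loa group=Nematoda
CCCAGGAGCGTGAACGTCGTGTGCAGTCTGAAGCTTCACGGTGAGGTAACGTGCTAGAACGCATAAAGCTACGATTCTAC
TCCCAGATGTCATGACGTAGCTATCGCCAAGCTCTTCCGTGTCTCTGGACAGCCAGGGGTTAGTCGGTAGTCATTGCTTC
TTTACATCTCTCACATACTGCGAGTGCCGAGCTCGGATATCCACTTCAAGCGAAATGGCGGT
>Setaria_labiatopapillosa group=Nematoda
CCCAGGAGCGTGAACGTCGTGTGCAGTGTCGGGGGTCAGAAATCAGTCCATTTAATTCCAAGACGAGTGGACTAGCAGTT
GCCGTTGGTGTCCAGCGCGACGCTAATACACCTGCAAATGAGCTTCAATTGGATAGGGGTGTAAGATGACAAAGTCCCAT
ATCTGCTATTGAATATACTGCCATCGAACGGGCATCGTATCCACTTCAAGCGAAATGGCGGT
>Parathelohania_anopheles group=Microsporidia
CCCAGGAGCGTGAACGTCGTGTGCAGTTCCCTAAGAACAGCGGCACGCTTATATAGCCCATTGCGAGGAGGATCGGGCCG
CAAAAATTAACTCACCTGCTAAGGAGCCATGCGGTGCCTGGAGCTGCCTTCTGGCGCTCCCGGCGGGTAGAATATCTGTA
AATGGCCAGAAGTGTCGTAATAGAGAGAGACATTGCCTATCCACTTCAAGCGAAATGGCGGT
>Anopheles_flavivirus_v1 group=Flavivirus
CCCAGGAGCGTGAACGTCGTGTGCAGTGCGGGGATATCTATAGTGCTTAAATCCTCCTTTTTTTATTGGTTCACACAAGG
ATCTATCTAAGGAGGCGGCGACTCAGGGTCGGCCAAGAAGAGCTGTAATCGCACTAACGTAAACTCTAACTTTGGCGTTT
CGGCCATTATGGTATTAAAGCACCAACTGCACTAGATTATCCACTTCAAGCGAAATGGCGGT
>Anopheles_flavivirus_v2 group=Flavivirus
CCCAGGAGCGTGAACGTCGTGTGCAGTGCGGGGATATCTATAGTGCTGAAATCCTCCTTTTTATATTGGTTCACACAAGG
ATGCATCTAAGGAGGCGGCGACTCAGGGTAGGACAAGAGCAGCTGTGATCGCACTAACGTAAACTCTAACTTTGGCGTTT
CGGCCATTATGGTATTAAAACACCGACTGCACTCGATTATCCACTTCAAGCGAAATGGCGGT
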