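>org1 Organism_1
AACAACCAAAGACCAAAGAGGGAAAGAAGAAAACACGACAAAAGAGAAAAACGAGAAGAAAAAAAAAAAAAAAAGAAAAA
AAACCGAAGAAAAACCGGAAAGGAAAAAAGAAAAAAGCAGGAACGAGAGAAAAGGGACAAAAGAAGAAAACAAAAAAAAA
GAAAAAGAGGGGAAGGGGAAAGAAAAAAGGGAGAAACAAAAAAAAGAAAGAAACAGAAAAAAAATGAGAAAAAAAAAAAC
AAAAAGAAAA
>org2 Organism_2
AGAACAAGAAATGAAAAGGAAGAAATCAAAAACGAACAGCCAAAAGCATGGCAAAGGGATAAATAAACATCAGAAGGGCG
GGGACGGGCAAAAGAGCAAATGGAAGTACAATGGAGGCCGAAGGATACAAAAGAGAAAGAAAGCTGAGAGGGGAACAAAA
GGCATAGATGAAAGGAAAGTTAATAAGAAATAACCGGGCAGAGTATATAAACGTAGAGAAAAAGTATGACAAGAAGAAAA
GTCTAGGACG
>org3_v1 Organism_3
CTACCTTTCCCGCTCCCGCGGGCCCCCTCCTTCACCTCCTTCGTTCCAACTCGCAGCTCCCCCGCCCTCCCCCTCGGCCC
CCTCTCTCCTCCCCCTTCCGTCCTGCTCCAGCAGTCCCCCCGGCGCTTCGCCGCCCCCCCCCGTACGCCTTTCGGCTTAG
CTCCTTTCCCTGGCTGTCCCTCTCCCGCCCTCAAGCCCTTGATTAGCCGGCCCCCCCTCAAATCCTTGCCTCCCCTCGGT
ATTCCTCCTC
>org3_v2 Organism_3
CTACCTTTCCCGCTCCCGCGGGCCCCCTCCTTCACCTCCTTCGTTCCAACTCGCAGCTCCCCCGCCCTCCCCCTCGGCCC
CCTCTCTCCTCCCCCTTCCGTCCTGCTCCAGCAGTCCCCCCGGCGCGTCGCCGCCCCCCCCCGTACGCCTTTCGGCTTAG
CTCCTTTCCCTGGCTGTCCCTCTCCCGCCCTCAAGCCCTTGATTAGCCGGCCCCCCCTCAAATCCTTGCCTCCCCTCGGT
ATTCCTCCTC
>org4 Organism_4
GGGGGGAGCCCAGGCGCGGGAGGGGGGGGCCGCAGCCGCCGGGCGCCGGCGCAGAACGGGCGGGGCCGCGCGGACACCCA
GGGCCGGCGGAGGCCGGGGCAGGCGGGAACCTCGGCTTGCCGGGGGAAACGGGGCGGGGCGGCCGGGGCGCCCCCGCGCG
AGGCGGGCCGGGGCGGGGCGGCGGCCGCCGGCGGGCGCCGGCCGCGCGGGCGGCGCGGGGGGGTAAGGGGCACGGAGGCC
GCCTGCGGCG
>org5 Organism_5
CCAAAAAAGACGAAAAGACCAGACAGACAAAAAGAACAAAACACCAAGCAACCAGCCAACCACAAACCAAAAAAAAGACA
AAAAACAGCAGAACAAAAAAAAACAACCCAAAGATAAAACCAAACACAAGCAACAAACACGCAACGGAACAAAACACAAG
CAACACAACCAAAAACACGACCCACCCAACAAAAGCCCAAACAGAACAACCACAACAAAACCAAAAAACCAAACACGAAA
CCCCAACAAA
>org6 Organism_6
CCCATCTCACCTTTTCTCTTCTTCTTCTTCTTTCTTCTTCTTTCTTCTTTTTTTGTCTTCTTCTTTATTTTTTTTCTCTT
TTCTTTTTTTTCTTCTTGCTGTTCCTAACTCTGTTCTACTCCCCCATCTTATTTTTCTTCCTTTTCTTCTTCTTCTGGTT
TTGTCCTTTTCCCTTTGTATCCTTTCTCTATTTCACTTCTTTCCCTATCTGTTCCACTTTCTCCCTCCTCCTTTTTGCTT
CTGCTTGTTT
>org7 Organism_7
CCCAACCATTTCATAGCAAACGTTGTTGCGGCGTACCCCCACTTCCGGCTACACCGACTCCGCTAAAGAGTTACTACACC
ACACTCCGTTCCCAACATCACGCGGCTCCCTAAACCTTATTGACGCCTATACAAATACAAGCTCCGGCACCCACAAACCT
CAGCGCCACCGCGGCACGGAATACAAGAACGCAATACAATGTACGCGCTAAGAAACGTCAAAAAACCGATAAGCTCGTCT
ACATATCGGT
>org8 Organism_8
GTATCTCCGGCCGGCTGGCTGGGCTTTTTTCTTCGGTTCGCTTTTCTTTCCAGTCTGTAGTCTCTCCCGCCGTTCTCGTA
TAGTGTGCGTTTTGTATAGGGCCGTGCTTCTTGCTTGTTCTGTAGCGCGCTTTTTCGCGGATCATTTTCAGGCCGGCTTT
TGGTCTGCCTGTTCGTGGCTTTTTTGTTTCTGCCCATTGGGTCCGTGTGGTGGGCGTTCGGCGGGTATGTTTGTTTTGTG
GTTTCTTGGG
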