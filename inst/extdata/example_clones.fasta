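>CA487_c01
ACCAATGCGAAACCCGACACAGTTACGTTTCCTGCTCCTCTCACTGTGAGCCAATGGACACCATCCCGAG
GGGTTAGATCAACCACAGTCACTGGATTCGCCTGGTGACCCAAATACAGAAAACTGGCGAACTTTAATTG
GCTGGACGATCGTAAGATTTTATGCTACCATGAGACGACGTCTGTTGGTAAGCCGTCTGTCCGGCGTCCT
CTCTCTCCTGATAAAGCCAATAACTAGACGTTGTCGTTCACTTTGACAACGTCGTGAGGCGTATCGTACA
TCTCAACCGCAGAGCCAGGAATCGAGCAACCGGCCTGGACATGCATCCTACAGAGATAGTTCTCATCATC
AAGCAGATCGCACTCATCTCGTAACGAAACTGTAGACCCTGTCACTCATCGACCATACCTAACGAACACA
CGGGTTAAACTAGGAACTGTAGGTAGTCTTCCGGGTCCCGTTGCAAGGAACTCCTCGTGTCAGAAAGTGT
CTTTCCTCAAAAGAATTTTTTCTCAACAAGTTAATACACATGAACGATCTGACTTAGTGCCTCATTATGC
GCGACGTCCTGTAGGTCGCGATCGATCAGAGGCACCTCACCCCCCTGGTTTTTGCTGTTGGTCTCTTTGT
GTCTCCATTATACCCCACTCATTCTATACTCT
>CA487_c02
ACCAATGCGAAACCCGACACAGTTACGTTTCCTGCTCC-CTCACTGTGAGCCAATGGACACCATCCCGAG
GGGTTAGATCAACCACAGTCACTGGATTCGCCTGGTGACCCAAGTACAGAAGACTGGCGGACTTTAATTG
GCTGATCGATCGTAAGATTTTATGCTACCATGAGACGACGTCTGTTGGTAAGCCGTCTGCCCGGCGTCCT
CTCTCTCCTGATAAAGCCAATAACTAGACGTTGTCGTTCACTTTGACAACGTCGTGAGGCGTATCGTACA
TCTCAACCGCAGAGCCAGGAATCGAGCAACCGGCCTGGACATGCATCCTACAGGGATAGTTCTCATCATC
AAGCAGATCGCACTCATCTCGTAACGAAACTGTAGACCCTGTCACTCATCGACCATACCTAACGAACACA
CGGGTTAAACTAGGAACTGTAGGTAGTCTTCCGGGTCCCGTTGCAAGGAACTCCTCGTGTCAGAAAGTGT
CTTTCCTCAAAAGAATTTTTTCTCAACAAGTTAATACACATGAACGATCTGACTTAGTGCCTCATTATAC
GCGACGTCCTGTAGGTCGCGATCGATCAGAGGCACCTCACCCCCCTGGTTTTTGCTGTTGGTCTCTTTGT
GTCTCCATTATACCCCACACATTCTATACTCT
>CA487_c03
ACCAATGCGAAACCCGACACAGTTACGTTTCCTGCTCC-CTCACTGTGAGCCAATGGACACCATCCCGAG
GGGTTAGATCAACCACAGTCACTGGATTCGCCTGGTGACCCAAATACAGAAGACTGGCGGACTTTAATTG
GCTGATCGATCGTAAGATTTTATGCTACCATGAGACGACGTCTGTTGGTAAGCCGTCTGCCCGGCGTCCT
CTCTCTCCTGATAAAGCCAATAACTAGACGTTGTCGTTCACTTTGACAACGTCGTGAGACGTATCGTACA
TCTCAACCGCAGAGCCAGGAATCGAGCAACCGGCCTGGACATGCATCCTACAGAGATAGTTCTCATCATC
AAGCAGATCGCACTCATCTCGTAACGAAACTGTAGACCCTGTCACTCATCGACCATACCTAACGAACACA
CGGGTTAAACTAGGAACTGTAGGTAGTCTTCCGGGTCCCGTTGCACGGAACTCC-CGTGTCAGAAAGTGT
CTTTCCTCAAAAGAATTTTTTCTCAACAAGTTAATACACATGAACGATCTGACTTAGTGCCTCATTATGC
GCGACGTCCTGTAGGTCGCGATCGATCAGAGGCACCTCACCCCCCTGGTTTTTGCTGTTGGTCTCTTTGT
GTCTCCATTATACCCCACTCATTCTATACTCT
>CA487_c04
ACCAATGCGAAACCCGACACAGTTACGTTTCCTGCTCC-CTCACTGTGAGCTAATGGACACCATCCCGAG
GGGTTAGATCAACCACAGTCACTGGATTCGCCTGGTGACCCAAATACAGAAGACTGGCGGACTTTAATTG
GCTGATCGATCGTAAGATTTTATGCTACCATGAGACGACGTCTGTTGGTAAGCCGTCTGCCCGGCGTCCT
CTCTCTCCTGATAAAGCCAATAACTAGACGTTGTCGTTCACTTTGACAACGTCGTGAGACGTATCGTACA
TCTCAACCGCAGAGCCAGGAATCGAGCAACCGGCCTGGACATGCATCCTACAGAGATAGTTCTCATCATC
AAGCAGATCGCACTCATCTCGTAACGAAACTGTAGACCCTGTCACTCATCGACCATACCTAACGAACACA
CGGGTTAAACTAGGAACTGTAGGTAGTCTTCCGGGTCCCGTTGCACGGAACTCC-CGTGTCAGAAAGTGT
CTTTCCTCAAAAGAATTTTTTCTCAACAAGTTAATACACATGAACGATCTGACTTAGTGCCTCATTATGC
GCGACGTCCTGTAGGTCGCGATCGATCAGAGGCACCTCACCCCCCTGGTTTTTGCTGTTGGTCTCTTTGT
GTCTCCATTATACCCCACTCATTCTATACTCT
>CA487_c05
ACCAATGCGAAACCCGACACAGTTACGTTTCCTGCTCCTCTCACTGTGAGCCAATGGACACCATCCCGAG
GGGTTAGATCAACCACAGTCACTGGATTCGCCTGGTGACCCAAATACAGAAAACTGGCGAACTTTAATTG
GCTGGACGATCGTAAGATTTTATGCTACCATGAGACGACGTCTGTTGGTAAGCCGTCTGTCCGGCGTCCT
CTCTCTCCTGATAAAGCCAATAACTAGACGTTGTCGTTCACTTTGACAACGTCGTGAGACGTATCGTACA
TCTCAACCGCAGAGCCAGGAATCGAGCAACCGGCCTGGACATGCATCCTACAGAGATAGTTCTCATCATC
AAGCAGATCGCACTCATCTCGTAACGAAACTGTAGACCCTGTCACTCATCGACCATACCTAACGAACACA
CGGGTTAAACTAGGAACTGTAGGTAGTCTTCCGGGTCCCGTTGCACGGAACTCC-CGTGTCAGAAAGTGT
CTTTCCTCAAAAGAATTTTTTCTCAACAAGTTAATACACATGAACGATCTGACTTAGTGCCTCATTATGC
GCGACGTCCTGTAGGTCGCGATCGATCAGAGGCACCTCACCCCCCTGGTTTTTGCTGTTGGTCTCTTTGT
GTCTCCATTATACCCCACTCATTCTATACTCT
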