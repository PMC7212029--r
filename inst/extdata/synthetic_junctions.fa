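>PTPRK-RSPO3 gene=RSPO3 breakpoint=80
TGCCTATACGACGCGCGTCTCTGTGTCTCATGTATGGGTCTAGGTAGGTACACCCTGCTAAGTAACCCTAGAAGATTTTT
CCGTAATTTTCAAAGTTCACGCGGGATCTCAATGTCGATTTCTCTCCGGCTGGGTCAACTATGTGTAGGGGTTATCCTTG
>EIF3E-RSPO2 gene=RSPO2 breakpoint=80
GAGGGCATTATATAACGCAGCCAACGCGATTCAACATGACAATCACTGAAGGATTGGGTATCGGCCAGACATCGACGAGC
AGCCAAAGCGTACGGACGTACGAATAATGCAGTTGAGCTTGTGGTCGCAGGTTGGACATATCGAGGGTGTCCCTTTGTCT
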