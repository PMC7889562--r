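>ChrSp08_oligo01
CCACGCTCAAGCAAGAACAAGACCCTTTGAGGAAGAAGAAGAAAC
>ChrSp08_oligo02
AGAAGAAGAAGAAGCAATGGTATCCATGGAATTTCTTTCACCTAC
>ChrSp08_oligo03
GGGGAAATTTCTGAGGATTTTTCTTGCTCTCCTTCTTCTTCTTCT
>ChrSp08_oligo04
GAAGAAGAAGAAATAATGGTGCAGCTGGTTCGCTGTTCATCTTAG
>ChrSp08_oligo05
GAAGAAGAAGAAAGCATTGGAAAGAAATCTTAGGAAGGTCGATGG
>ChrSp08_oligo06
AGAGAGAGAGAGAAGTAGATAGGTGATGGCAAGATGGTCGTTGCG
>ChrSp08_oligo07
TCTCTCTCTCTCTAAGATCCTCTTTGGTACATGGAAGGTACCGTG
>ChrSp08_oligo08
AGAGAGAGAGAGAAATGCTCAAGACACATTTGACTTCTGCGTATG
>ChrSp08_oligo09
GAGAGAGAGAGAGCATAGGGGTTCAATGTCTAGTGACTAGATGCC
>ChrSp08_oligo10
GAGAGAGAGAGATTATCATGATGCTGTCTTATGTCAATCAAAGGC
>ChrSp18_oligo01
AGAAGAAGAAGAAGAGGATAGAACCGTTTGACGACCTCTCTTTCC
>ChrSp18_oligo02
CTTCTTCTTCTTCTGGGTTCGATCAGTCTGTGCGTGAAGGGGTAC
>ChrSp18_oligo03
AGGAGGAGCAGAAACCTAGAAGAAGAAGAAGCTCACGTTCTTCCG
>ChrSp18_oligo04
CTTCTTCTTCTTCATAAGTCTACCGGCCGGATAACCAGAAGTGAG
>ChrSp18_oligo05
AGAGAGAGAGAGAGTTAAATAGGACGTACAATTCCTACGAACCAA
>ChrSp18_oligo06
CTCTCTCTCTCTACATTCTGGTGCATCGACACAGAGATAGATCCT
>ChrSp18_oligo07
TCTCTCTCTCTCTTCGTTAAGAAAACATCTTGTTGGACTAGACGT
>ChrSp19_oligo01
AGTATCATCAAGTGAAGAAGAAGAATGCTTGACACAGGCTCGTTC
>ChrSp19_oligo02
AAGAAGAAGAAGAAGCAATTGGAAAAAGAACTCGCGGCTGTCTGA
>ChrSp19_oligo03
AAATCCAGCGATGGAACCATCATGGAGGTCCTTCTTCTTCTTCTT
>ChrSp19_oligo04
GAGAGAGAGAGAGATGTAAATAAGTCAACTGGTGATGATGCCACT
>ChrSp19_oligo05
CTCTCTCTCTCTAGAATACCATGCAGATCAGGAATGTGCAAAACC
>ChrSp19_oligo06
AGAGAGAGAGAGAATTTGTGTGCAGTGACCGAGTCCTTACTCTCT
>ChrSp19_oligo07
AGAGAAAGTACAGAGAGAGAGAGATTGAGGCACCTGAAGACCGGC
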