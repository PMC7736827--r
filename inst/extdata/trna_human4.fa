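>Gly-GCC-2 Homo sapiens mature tRNA-Gly-GCC isodecoder 2, no CCA
GCATTGGTGGTTCAGTGGTAGAATTCTCGCCTGCCACGCGGGAGGCCCGGGTTCGATTCCCGGCCAATGCA
>Glu-CTC-1 Homo sapiens mature tRNA-Glu-CTC, no CCA
TCCCTGGTGGTCTAGTGGTTAGGATTCGGCGCTCTCACCGCCGCGGCCCGGGTTCGATTCCCGGCCAGGGAA
>Lys-TTT-3 Homo sapiens mature tRNA-Lys-TTT, no CCA
GCCCGGATAGCTCAGTCGGTAGAGCATCAGACTTTTAATCTGAGGGTCCAGGGTTCAAGTCCCTGTTCGGGCG
>iMet-CAT-1 Homo sapiens mature initiator tRNA-iMet-CAT, no CCA
AGCAGAGTGGCGCAGCGGAAGCGTGCTGGGCCCATAACCCAGAGGTCGATGGATCGAAACCATCCTCTGCTA
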