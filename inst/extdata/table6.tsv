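gene	isoform	seq1	comp1	seq2	comp2
HaAPN1	C1	AACTACGATCAAATCACTTG	TCAAA	ATTTTGAAC*G*AAATCACAGC	TTTGA
HaAPN1	C2	TAACTACGATCAAATCACTT	-	GAATGAAGC*C*CAAATCACTC	-
HaAPN1	C3	GGGAATGGGTTATTTTCAAT	TCAA	GCGTCAGTC*C*TATTTTGAAC	TTGA
HaAPN1	C4	TTTGACAACCTGAAACCTAC	-	GCCTATTGA*A*TGAAGCCCAA	-
HaAPN1	C5	TGGACTAGGGCAGGATCTAT	-	CCAAATCAC*T*CAGGTAACATT	-
HaAPN1	C6	TGAGCGCAATACTGGTGTAT	GAGC	GAACGAAAT*C*ACTGCTCGCC	GCTC
HaAPN1	C7	CATTGTTGACTGTGTCCATT	TTGAC	TAAAACCTA*A*TGTGTCAACT	GTCAA
HaAPN1	C8	CATCCCCATTACTTGGACTA	-	TCAGGTTCA*A*ACTTGGTTGA	-
HaAPN1	C9	GCAACCGCAGACAATGCTCT	-	GAACGAAAT*C*ACAGCTCGCC	-
HaAPN1	C10	CACTTACTGGGCAACAACAC	-	AGGCTAATG*T*GCAACAGACT	-
HaAPN1	C11	CTGTCAGCGCACACTTCTCC	-	CAGACTATA*A*ACACGTACGT	-
HaAPN1	C12	GTATCAACAGCGACCGACAG	-	GAAGCGCCT*A*CGACCACAAC	-
HaAPN1	C13	CTTCTCCACCATCACTTATG	CTTC	TGAAGCCCA*A*ATCACTCAGG	GAAG
HaAPN1	C14	CTTACTGGGCAACAACACTT	-	GTCTAGGTC*C*AACATTCAGT	-
HaAPN3	C1	CGCTTCTCCCTACCGTCTGC	CGTCT	TTGAAGACG*T*TACCGCGGTA	AGACG
HaAPN3	C2	ACATTGATCCCCACCACCCC	-	CTGAACCTT*A*CCACCACTCG	-
HaAPN3	C3	GAAGGAACATTGATCCCCAC	AAGGA	CAAACTTGG*C*TGATCCTTAC	TCCTT
HaAPN3	C4	CAAGGAACGGCAACGGAAGG	-	ACAATAACA*T*CAACGGAGAC	-
HaAPN3	C5	TCAATCTCAATACCACTTCT	-	GGCTGAACC*T*TACCACCACT	-
HaAPN3	C6	GCCAAGTTTGACGTTACGAT	ACGT	ACTGTTGAA*G*ACGTTACCGC	ACGT
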