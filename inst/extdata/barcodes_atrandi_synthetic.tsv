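#set	well	sequence
D	D01	GCGCCAGT
D	D02	TAGCCGGA
D	D03	ACCCAACA
D	D04	CGATACTG
D	D05	TGTTACTG
D	D06	GAGTAGTC
D	D07	ATTCCTGA
D	D08	TGCCCCTG
D	D09	TTGTTTTT
D	D10	GAAAGACC
D	D11	ATACAATC
D	D12	ACGCTTGT
D	D13	ATATCCCA
D	D14	CTCAATCT
D	D15	ACGCTCAT
D	D16	TGCGAACT
D	D17	GATGCGTG
D	D18	TTGACGAG
D	D19	ATTTCTTC
D	D20	GGGAGGTT
D	D21	TGTGCTTT
D	D22	GAAAACAG
D	D23	CTACCAGC
D	D24	CACGCACT
C	C01	CCGAAGGC
C	C02	AACGCGAC
C	C03	CATTTGTT
C	C04	CGCGCGGG
C	C05	CTAAGATC
C	C06	TCAGGTAT
C	C07	ATTGGAGA
C	C08	CGCGGATT
C	C09	CGGGCTAC
C	C10	TCTGGCAG
C	C11	ATGAGAAA
C	C12	TCCATCCC
C	C13	TAGCGGAC
C	C14	AGCGACTT
C	C15	CTAGGAAG
C	C16	TGTACACC
C	C17	ATCCTATC
C	C18	CATGGTGG
C	C19	TTATTATG
C	C20	GCGTCAGT
C	C21	GGGCACCA
C	C22	GGCGTCCA
C	C23	GTATGCGC
C	C24	CTACTTGG
B	B01	TGCAACTC
B	B02	GCGTGCAT
B	B03	GCGCTGAT
B	B04	GATGAACT
B	B05	TCGGAACG
B	B06	ACGGCAAC
B	B07	CCGCACCA
B	B08	CGCTTAGG
B	B09	GCTTATGC
B	B10	GAGTATTC
B	B11	ATCATCGA
B	B12	ATGCTCTC
B	B13	GGCGCAGC
B	B14	GGACGCGT
B	B15	ATAATGCG
B	B16	GCTATCTC
B	B17	CATGAGAA
B	B18	TCTCGTCC
B	B19	TAACGTCT
B	B20	GCCTTTAA
B	B21	CGGCTTGT
B	B22	GATGAATT
B	B23	TCTAAAGC
B	B24	ATTGAAGG
A	A01	CGATACTA
A	A02	AGATGAGT
A	A03	TAACGAAC
A	A04	ATTAGCGG
A	A05	ACCACCTA
A	A06	AAAGTCTT
A	A07	CGCACTTA
A	A08	ACCTTCAG
A	A09	TAAACAAG
A	A10	GGCACCGT
A	A11	CCGCAATC
A	A12	GCGTGTCA
A	A13	TCTCTTCA
A	A14	TTACGCTT
A	A15	TGTCTCTG
A	A16	CTGCTTCG
A	A17	GCGCCGCT
A	A18	TGCATCTA
A	A19	ATAGTCGA
A	A20	GCGCGTGC
A	A21	CACCGGAA
A	A22	CGGTTAGA
A	A23	GTCTTGCC
A	A24	CAGCTCGC
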