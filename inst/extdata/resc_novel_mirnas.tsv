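mature_sequence	precursor_location	name	reads_IVF1.2	reads_IVF3.2	reads_IVF3.3
TATGGAGGTCTCTGTCTGGCT	chr1:205580537-205580616:-	miR-1843-5p	124	159	152
TCTGATCGTTCCCCTCCATACA	chr1:205580537-205580616:-	miR-1843-3p	127	174	193
TGATGGGTGAATTTGTAGAAGG	chr1:70976129-70976208:-	miR-1262-3p	2557	2267	2150
GTTGGGACAAGAGAACGGTCTT	chr1:158332926-158333000:-	miR-3122-5p	252	371	214
AATTCCCTTATGGATAATCTGG	chr2:80519804-80519882:+	miR-3938-3p	138	227	104
CATGCTAGAACAGAAAGAATGGG	chr3:106443245-106443327:+	miR-3146-3p	37	120	61
TATTTTGAGTGTTTGGAATTGA	chr4:125407861-125407939:+	miR-3145-3p	35	36	31
GAAAATGATGAGTAGTGACTGATG	chr4:128869861-128869951:+	miR-3622-3p	72	243	73
AAGAGCTTTTGGGAATTCAGGTAG	chr5:144708317-144708405:-	miR-3140-3p	151	358	200
ATATACAGGGGGAGACTCTTAT	chr7:164327476-164327555:+;chr7:164328696-164328775:+	miR-1185-3p	52	176	105
CGGGAACGTCGAGACTGGAGC	chr7:164844819-164844896:-	miR-1247-3p	127	131	32
TTAGGGCCCTGGCTCCATCTCC	chr9:73887081-73887164:+	miR-1296-5p	33	123	53
TCGACCGGACCTCGACCGGCTCG	chr9:103084702-103084783:-	miR-1307-5p	291	872	944
ACTCGGCGTGGCGTCGGTCGTGG	chr9:103084702-103084783:-	miR-1307-3p	1936	3975	3030
GACTCTAGCTGCCAAAGGCGCT	chr11:98713141-98713223:+	miR-1251-5p	40	97	59
TGTGGGACCTCTGGCCTTGGC	chr11:105706113-105706195:+	miR-3922-3p	192	250	248
TGCGGGGCTAGGGCTAACAGCA	chr16:11829804-11829901:+	miR-744-5p	11447	24797	14171
CTGTTGCCACTAACCTCAACC	chr16:11829804-11829901:+	miR-744-3p	75	81	104
TTTCCGGCTCGCGTGGGTGTGT	chr16:18891345-18891423:-	miR-1180-3p	30	133	77
CCGTCCTAAGGTTGTTGAGTT	chrX:68990098-68990174:+	miR-676-3p	46	206	206
TTCATTCGGCTGTCCAGATGTA	chrX:113236410-113236505:+	miR-1298-5p	246	893	852
CATCTGGGCAACTGACTGAACT	chrX:113236410-113236505:+	miR-1298-3p	30	98	58
TGAGTACCGCCATGTCTGTTGGG	chrX:113271154-113271232:+	miR-1911-5p	88	843	473
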