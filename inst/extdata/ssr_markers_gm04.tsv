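marker	chrom	pos	primer_f	primer_r
BARCSOYSSR_04_1390	Gm04	50549768	CCCGGTACAGTTGAGATGGA	TTGCACTTCAGTAGGCCCTC
BARCSOYSSR_04_1391	Gm04	50588500	AGATGGTGGTGTTCTCAGGG	ACCATCACCAACATGCAGAT
BARCSOYSSR_04_1418	Gm04	50942037	TTTTTCTTCAGAAACTTGAAACATT	TGCATTTCTGAAACAAGGCAT
BARCSOYSSR_04_1420	Gm04	50953149	AAGTGATCAATGTTATCGATGAAGTA	TTTGTCTCAATTAGTGTGGAATTTG
BARCSOYSSR_04_1426	Gm04	51011052	ATCAGAGGTCTGCCACCAAT	CGCTGACAGACACCAAGAGA
BARCSOYSSR_04_1429	Gm04	51035485	TTTGCTACAGTGCTATCGGC	TGCCAGCCGCTTATCTATCT
BARCSOYSSR_04_1435	Gm04	51111716	GTCCGTGCCAGTTTTTCATT	TGCTGCACTTTCTCCTGATG
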