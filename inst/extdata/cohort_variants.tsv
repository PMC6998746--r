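gene	variant	type	classification	n_detected
BRCA1	c.68_69del (p.Glu23Valfs*17)	DEL	P	1
BRCA1	c.211A>G (p.Arg71Gly)	SNV	P	1
BRCA1	c.406dupA (p.Arg136Lysfs*6)	INS	P	1
BRCA1	c.427G>T (p.Glu143*)	SNV	P	1
BRCA1	c.1960A>T (p.Lys654*)	SNV	P	1
BRCA1	c.3193dup (p.Asp1065Glyfs*2)	INS	P	1
BRCA1	c.4327C>T (p.Arg1443*)	SNV	P	2
BRCA1	c.5266dup (p.Gln1756Profs*74)	INS	P	1
BRCA1	c.5353C>T (p.Gln1785*)	SNV	P	1
BRCA1	c.3598C>T (p.Gln1200*)	SNV	P	1
BRCA1	Exon 13 duplication	CNV	P	1
BRCA2	c.755_758del (p.Asp252Valfs*24)	DEL	P	1
BRCA2	c.1265del (p.Asn422Ilefs*8)	DEL	P	1
BRCA2	c.3922G>T (p.Glu1308*)	SNV	P	1
BRCA2	c.4284dup (p.Gln1429Serfs*9)	INS	P	1
BRCA2	c.4631dup (p.Asn1544Lysfs*4)	INS	P	1
BRCA2	c.5290_5291del (p.Ser1764Lysfs*3)	DEL	P	1
BRCA2	c.5385dup (p.Asp1796Argfs*11)	INS	P	1
BRCA2	c.5681dup (p.Tyr1894*)	INS	P	1
BRCA2	c.5682C>G (p.Tyr1894*)	SNV	P	1
BRCA2	c.5946del (p.Ser1982Argfs*22)	DEL	P	2
BRCA2	c.6373dup (p.Thr2125Asnfs*4)	INS	P	1
MUTYH	c.536A>G (p.Tyr179Cys)	SNV	P	1
MUTYH	c.1187G>A (p.Gly396Asp)	SNV	P	6
MUTYH	c.1214C>T (p.Pro405Leu)	SNV	P	1
MUTYH	c.1477G>T (p.Val493Phe)	SNV	P	1
CHEK2	c.444+1G>A	SNV	P	1
CHEK2	c.793-1G>A	SNV	P	1
CHEK2	c.1100delC (p.Thr367Metfs*15)	DEL	P	5
CHEK2	c.1169A>C (p.Tyr390Ser)	SNV	LP	1
ATM	c.7638_7646del (p.Arg2547_Ser2549del)	DEL	P	1
ATM	c.8395_8404del (p.Phe2799Lysfs*4)	DEL	P	1
PALB2	c.2642_2645dup (p.Cys882Trpfs*3)	INS	P	1
PALB2	c.3256C>T (p.Arg1086*)	SNV	P	1
PMS2	c.809C>G (p.Ser270*)	SNV	P	1
PMS2	Exon 7-8 deletion	CNV	P	1
CDH1	c.1565+1G>C	SNV	P	1
BARD1	c.1690C>T (p.Gln564*)	SNV	P	1
CDKN2A	c.301G>T (p.Gly101Trp)	SNV	P	1
MLH1	c.793C>T (p.Arg265Cys)	SNV	P	1
RAD51C	c.773G>A (p.Arg258His)	SNV	LP	1
RET	c.2410G>A (p.Val804Met)	SNV	P	1
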