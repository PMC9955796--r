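name	consensus	stress
GCN4	TGACTC	1
GCR1	CWTCC	1
ADR1	TTGGRG	1
STRE	AGGGG	1
HSTF	GAANNTTC	1
PHO4	CACGTK	1
GC/FAR	GGGCGG	1
ABF1	RTCRYNNNNNACG	1
TATA	TATAWAW	0
CAAT	CCAAT	0
MCB	ACGCGT	0
SCB	CNCGAAA	0
RAP1	RMACCCANNCAYY	0
MIG1	SYGGGG	0
GAL4	CGGNNNNNNNNNNNCCG	0
URS1	AGCCGCCGA	0
CSRE	CGGAYRRAWGG	0
LEU3	CCGNNNNCGG	0
INO4	CATGTGAA	0
MET31	AAACTGTGG	0
PDR3	TCCGCGGA	0
AP1	TGACTAA	0
XBP1	CTTCGAG	0
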