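UniProt_code	Start	End	Length
A0A023C4T7_9PSED	88	148	60
A0A0B2AVS1_9ACTN	85	145	60
A0NP21_LABAI	80	140	60
I9W6R0_9RALS	87	147	60
W4CMK3_9BACL	121	181	60
A0A074LC92_PAEPO	82	143	61
I4N7I5_9PSED	87	148	61
A0A0D5NE20_9BACL	85	147	62
F8FPR4_PAEMK	106	168	62
G8QJ34_DECSP	85	147	62
V7DIJ8_9PSED	88	150	62
W4P2V0_9BURK	87	149	62
B9QZW6_LABAD	80	143	63
F3KUT6_9BURK	118	181	63
F7T5G0_9BURK	85	148	63
M2X958_9MICC	80	143	63
R9LS02_9BACL	83	146	63
S2WJB8_DELAC	89	152	63
A0A098SWK7_9PSED	88	152	64
A0A0J6J2M6_9PSED	88	152	64
A0A0F4KHT0_9ACTN	101	166	65
D5BN74_PUNMI	82	147	65
D7DQ74_METV0	90	156	66
K0YXF4_9ACTN	79	145	66
A0A077LFC1_9PSED	87	154	67
A0A095YU49_9FIRM	78	145	67
H0BWG7_9BURK	75	142	67
A0A087DUC1_9BIFI	78	146	68
A0A090ZGE9_PAEMA	83	152	69
A0A0A6Q9N6_9BURK	74	143	69
F3JEN8_PSESX	88	157	69
W0HH53_PSECI	88	157	69
A0A0A6QBJ9_9BURK	89	159	70
A0A0B4DLS5_9MICC	89	159	70
A0A088Y9M0_BURPE	88	159	71
A0A0F4JB47_9ACTN	62	135	73
A0A069DE36_9BACL	85	159	74
A0A087EGV8_9BIFI	105	181	76
A0A089I7M0_9BACL	82	158	76
A8SVX0_9FIRM	79	155	76
A0A089N895_9BACL	78	155	77
A0A0F5JX35_9BURK	84	161	77
A0A0E4CZM5_9BACL	90	168	78
A0A061LXN0_9MICO	84	163	79
A0A0A8BLT7_9BURK	89	168	79
R6HHE8_9ACTN	79	159	80
X4ZGS7_9BACL	84	164	80
A0A089HPN9_PAEDU	78	162	84
D2PX75_KRIFD	93	178	85
D3F8U9_CONWI	80	166	86
A0A0A4HID4_9PSED	88	179	91
F2RK57_STRVP	86	180	94
C7MPD0_CRYCD	79	174	95
F4QXL0_BREDI	83	179	96
A0A087AB73_9BIFI	78	175	97
A0A087E7D4_9BIFI	78	175	97
A0A0B4DPH0_KOCRH	85	183	98
F2RA50_STRVP	88	186	98
V6KRX5_STRRC	93	191	98
M8D4I1_9BACL	79	179	100
A0A0A3JRX6_BURPE	88	189	101
M8DED6_9BACL	80	183	103
A0A087BLK1_BIFLN	78	187	109
A0A087CXD8_9BIFI	78	187	109
S6CDU1_9ACTN	130	244	114
A0A0A6SYE7_9BURK	87	209	122
F5LR05_9BACL	82	209	127
A0A089IZ38_PAEDU	84	218	134
A0A0B6S8F7_BURGL	88	231	143
A0A087A119_9BIFI	78	222	144
A0A089MC10_9BACL	82	234	152
A0A089KZI8_9BACL	82	244	162
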