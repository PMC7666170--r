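class	training	testing
HCT-116	7151	3306
HL60	26298	1313
JURKAT	9208	3980
LNCAP	2555	1216
MCF7	4109	1702
PC3	4700	1908
THP-1	8656	1371
U2OS	15413	1069
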