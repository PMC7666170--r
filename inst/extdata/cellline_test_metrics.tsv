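class	precision	recall	f1
HCT-116	0.994	0.981	0.988
HL60	0.970	0.932	0.951
JURKAT	0.969	0.989	0.979
LNCAP	0.940	0.873	0.905
MCF7	0.950	0.969	0.960
PC3	0.960	0.981	0.970
THP-1	0.963	0.931	0.947
U2OS	0.896	0.953	0.924
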