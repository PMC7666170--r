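class	precision	recall	f1
JURKAT	0.918	0.977	0.946
LNCAP	0.985	0.974	0.979
RAJI	0.956	0.936	0.946
THP-1	0.973	0.962	0.967
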