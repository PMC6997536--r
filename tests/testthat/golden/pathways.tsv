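pathway_id	name	n_genes	n_targeted	proportion	n_validated
PW3	synthetic pathway PW3	20	3	0.150000	1
PW1	synthetic pathway PW1	34	5	0.147059	1
PW2	synthetic pathway PW2	20	2	0.100000	1
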