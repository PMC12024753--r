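mutation	cluster	WT	mutated
EGFR	sub0	131	33
EGFR	sub1	71	4
EGFR	sub2	239	25
KRAS	sub0	178	86
KRAS	sub1	59	16
KRAS	sub2	116	48
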