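fragment	components	weights	formula	sd
tri_p	TRI.p:1-3	NA		0.01
tri_c	TRI.c:1-3	NA		0.01
pyr	PYR.c:1-3	NA		0.015
pyr_23	PYR.c:2-3	NA		0.015
acc	ACC.p:1-2	NA		0.01
cit2	CIT2.c:1-2	NA		0.01
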