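fragment	components	weights	formula	sd
rubp_5	RuBP.p:1-5	NA		0.015
pga_3	PGA.p:1-3|PGA.c:1-3	0.67|0.33		0.01
gap_dhap	GAP.p:1-3|DHAP.p:1-3|DHAP.c:1-3	0.2|0.4|0.4		0.015
fbp_6	FBP.p:1-6|FBP.c:1-6	0.55|0.45		0.015
f6p_6	F6P.p:1-6|F6P.c:1-6	0.6|0.4		0.015
g6p_6	G6P.p:1-6|G6P.c:1-6	0.33|0.67		0.015
s7p_7	S7P.p:1-7	NA		0.01
sbp_7	SBP.p:1-7	NA		0.015
r5p_5	R5P.p:1-5	NA		0.015
ru5p_x5p	Ru5P.p:1-5|X5P.p:1-5	0.5|0.5		0.015
e4p_4	E4P.p:1-4	NA		0.02
pg2_2	PG2.p:1-2	NA		0.015
adpg_6	ADPG.p:1-6	NA		0.01
udpg_6	UDPG.c:1-6	NA		0.01
suc_361	SUC.c:1-6|SUC.c:7-12	0.46|0.54	C6H19O8Si3	0.01
suc_451	SUC.c:1-6|SUC.c:7-12	0.08|0.92	C8H27O9Si4	0.01
pep_3	PEP.c:1-3	NA		0.01
pyr_3	PYR.c:1-3|PYR.p:1-3	0.9|0.1		0.02
glyc_292	GLYC.p:1-3	NA	C9H24O2Si2	0.02
ala_260	ALA.c:1-3	NA	C8H20NOSi	0.02
ala_232	ALA.c:2-3	NA	C9H22NSi	0.02
gly_246	GLY.p:1-2	NA	C8H20NOSi	0.02
ser_390	SER.p:1-3	NA	C13H32NO2Si2	0.02
ser_362	SER.p:2-3	NA	C14H34NOSi2	0.02
asp_418	ASP.c:1-4	NA	C13H32NO3Si2	0.02
asp_390	ASP.c:2-4	NA	C14H34NO2Si2	0.02
glu_432	GLU.c:1-5	NA	C13H32NO3Si2	0.02
glu_330	GLU.c:2-5	NA	C11H28NOSi2	0.02
cit_465	CIT.m:1-6	NA	C14H37O7Si4	0.01
cit_375	CIT.m:1-5	NA	C11H29O5Si3	0.012
mal_419	MAL.c:1-4|MAL.m:1-4	0.8|0.2	C13H31O5Si3	0.01
mal_233	MAL.c:2-4|MAL.m:2-4	0.8|0.2	C9H21O2Si2	0.015
fum_245	FUM.m:1-4	NA	C7H17O2Si2	0.01
succ_289	SUCC.m:1-4	NA	C9H21O2Si2	0.01
akg_346	AKG.m:1-5	NA	C10H24NO4Si2	0.02
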