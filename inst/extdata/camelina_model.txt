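# Compartmentalized atom-transition model of photosynthetic leaf central
# metabolism (C3 cycle, photorespiration, starch & sucrose synthesis,
# glycolysis, PEP carboxylation, TCA-associated reactions, G6P/OPP shunt,
# plastidic fatty-acid precursor synthesis, intercompartment transport,
# lumped phloem export). Compartments: .p plastid, .c cytosol, .m
# mitochondrion. Carbon maps use letters a-z, 1-based positions left to
# right. Reconstructed leaf topology; dilution=yes marks metabolites with a
# metabolically inactive (vacuolar) pool.

@met CO2in carbons=1 source
@met CO2out carbons=1 sink
@met RuBP.p carbons=5 dilution=yes
@met PGA.p carbons=3 dilution=yes
@met GAP.p carbons=3 dilution=yes
@met DHAP.p carbons=3 dilution=yes
@met FBP.p carbons=6 dilution=yes
@met F6P.p carbons=6 dilution=yes
@met G6P.p carbons=6 dilution=yes
@met E4P.p carbons=4 dilution=yes
@met SBP.p carbons=7 dilution=yes
@met S7P.p carbons=7 dilution=yes
@met R5P.p carbons=5 dilution=yes
@met X5P.p carbons=5 dilution=yes
@met Ru5P.p carbons=5 dilution=yes
@met PG2.p carbons=2 dilution=yes
@met GLY.p carbons=2 dilution=yes
@met SER.p carbons=3 dilution=yes
@met GLYC.p carbons=3 dilution=yes
@met ADPG.p carbons=6 dilution=yes
@met PEP.p carbons=3
@met PYR.p carbons=3
@met ACA.p carbons=2
@met STARCH carbons=6 sink
@met FASINK carbons=2 sink
@met DHAP.c carbons=3 dilution=yes
@met GAP.c carbons=3 dilution=yes
@met FBP.c carbons=6 dilution=yes
@met F6P.c carbons=6 dilution=yes
@met G6P.c carbons=6 dilution=yes
@met UDPG.c carbons=6 dilution=yes
@met SUC.c carbons=12 dilution=yes
@met PGA.c carbons=3 dilution=yes
@met PEP.c carbons=3 dilution=yes
@met PYR.c carbons=3
@met OAA.c carbons=4
@met MAL.c carbons=4 dilution=yes
@met ALA.c carbons=3 dilution=yes
@met ASP.c carbons=4 dilution=yes
@met GLU.c carbons=5 dilution=yes
@met ACA.c carbons=2
@met OAA.m carbons=4
@met MAL.m carbons=4 dilution=yes
@met FUM.m carbons=4 dilution=yes symmetric=yes
@met SUCC.m carbons=4 dilution=yes symmetric=yes
@met CIT.m carbons=6 dilution=yes
@met AKG.m carbons=5 dilution=yes
@met MALSINK carbons=4 sink
@met GLUSINK carbons=5 sink
@met SINK carbons=0 sink

# --- C3 cycle ---
rbc_c: 1 RuBP.p (abcde) + 1 CO2in (f) -> 1 PGA.p (cba) + 1 PGA.p (fed) | reversible=no | co2=none
rbc_o: 1 RuBP.p (abcde) -> 1 PG2.p (ab) + 1 PGA.p (cde) | reversible=no | co2=none
pgk: 1 PGA.p (abc) -> 1 GAP.p (abc) | reversible=yes | co2=none
tpi_p: 1 GAP.p (abc) -> 1 DHAP.p (abc) | reversible=yes | co2=none
fba_p: 1 DHAP.p (cba) + 1 GAP.p (def) -> 1 FBP.p (abcdef) | reversible=yes | co2=none
fbp_p: 1 FBP.p (abcdef) -> 1 F6P.p (abcdef) | reversible=no | co2=none
tkt1: 1 F6P.p (abcdef) + 1 GAP.p (ghi) -> 1 X5P.p (abghi) + 1 E4P.p (cdef) | reversible=yes | co2=none
sba: 1 DHAP.p (cba) + 1 E4P.p (defg) -> 1 SBP.p (abcdefg) | reversible=yes | co2=none
sbp: 1 SBP.p (abcdefg) -> 1 S7P.p (abcdefg) | reversible=no | co2=none
tkt2: 1 S7P.p (abcdefg) + 1 GAP.p (hij) -> 1 R5P.p (cdefg) + 1 X5P.p (abhij) | reversible=yes | co2=none
rpi: 1 R5P.p (abcde) -> 1 Ru5P.p (abcde) | reversible=yes | co2=none
rpe: 1 X5P.p (abcde) -> 1 Ru5P.p (abcde) | reversible=yes | co2=none
prk: 1 Ru5P.p (abcde) -> 1 RuBP.p (abcde) | reversible=no | co2=none

# --- photorespiration ---
pglp: 1 PG2.p (ab) -> 1 GLY.p (ab) | reversible=no | co2=none
gdc: 1 GLY.p (ab) + 1 GLY.p (cd) -> 1 SER.p (abd) + 1 CO2out (c) | reversible=no | co2=pr
sgat: 1 SER.p (abc) -> 1 GLYC.p (abc) | reversible=no | co2=none
glyk: 1 GLYC.p (abc) -> 1 PGA.p (abc) | reversible=no | co2=none

# --- starch synthesis ---
pgi_p: 1 F6P.p (abcdef) -> 1 G6P.p (abcdef) | reversible=yes | co2=none
adpgs: 1 G6P.p (abcdef) -> 1 ADPG.p (abcdef) | reversible=no | co2=none
starch: 1 ADPG.p (abcdef) -> 1 STARCH (abcdef) | reversible=no | co2=none

# --- G6P/OPP shunt (6-phosphogluconate decarboxylation, lumped) ---
shunt: 1 G6P.p (abcdef) -> 1 Ru5P.p (bcdef) + 1 CO2out (a) | reversible=no | co2=release:shunt

# --- plastidic glycolysis and fatty-acid precursor synthesis ---
pgm_p: 1 PGA.p (abc) -> 1 PEP.p (abc) | reversible=no | co2=none
pk_p: 1 PEP.p (abc) -> 1 PYR.p (abc) | reversible=no | co2=none
pdh_p: 1 PYR.p (abc) -> 1 ACA.p (bc) + 1 CO2out (a) | reversible=no | co2=release:fa
fas: 1 ACA.p (ab) -> 1 FASINK (ab) | reversible=no | co2=none

# --- triose-phosphate export and sucrose synthesis ---
tpt: 1 DHAP.p (abc) -> 1 DHAP.c (abc) | reversible=yes | co2=none
tpi_c: 1 DHAP.c (abc) -> 1 GAP.c (abc) | reversible=yes | co2=none
fba_c: 1 DHAP.c (cba) + 1 GAP.c (def) -> 1 FBP.c (abcdef) | reversible=yes | co2=none
fbp_c: 1 FBP.c (abcdef) -> 1 F6P.c (abcdef) | reversible=no | co2=none
pgi_c: 1 F6P.c (abcdef) -> 1 G6P.c (abcdef) | reversible=yes | co2=none
udpgs: 1 G6P.c (abcdef) -> 1 UDPG.c (abcdef) | reversible=no | co2=none
sps: 1 UDPG.c (abcdef) + 1 F6P.c (ghijkl) -> 1 SUC.c (abcdefghijkl) | reversible=no | co2=none

# --- cytosolic glycolysis, anaplerosis, amino acids ---
gapdh_c: 1 GAP.c (abc) -> 1 PGA.c (abc) | reversible=yes | co2=none
eno: 1 PGA.c (abc) -> 1 PEP.c (abc) | reversible=yes | co2=none
pk_c: 1 PEP.c (abc) -> 1 PYR.c (abc) | reversible=no | co2=none
pepc: 1 PEP.c (abc) + 1 CO2in (d) -> 1 OAA.c (abcd) | reversible=no | co2=fix
ala_ta: 1 PYR.c (abc) -> 1 ALA.c (abc) | reversible=yes | co2=none
asp_ta: 1 OAA.c (abcd) -> 1 ASP.c (abcd) | reversible=yes | co2=none
mdh_c: 1 OAA.c (abcd) -> 1 MAL.c (abcd) | reversible=yes | co2=none
malsink: 1 MAL.c (abcd) -> 1 MALSINK (abcd) | reversible=no | co2=none

# --- TCA-associated reactions (noncyclic day-time operation) ---
pdh_c: 1 PYR.c (abc) -> 1 ACA.c (bc) + 1 CO2out (a) | reversible=no | co2=release:tca
oaat: 1 OAA.c (abcd) -> 1 OAA.m (abcd) | reversible=yes | co2=none
cs: 1 OAA.m (abcd) + 1 ACA.c (ef) -> 1 CIT.m (dcbfea) | reversible=no | co2=none
idh: 1 CIT.m (abcdef) -> 1 AKG.m (abcde) + 1 CO2out (f) | reversible=no | co2=release:tca
akgdh: 1 AKG.m (abcde) -> 1 SUCC.m (bcde) + 1 CO2out (a) | reversible=no | co2=release:tca
sdh: 1 SUCC.m (abcd) -> 1 FUM.m (abcd) | reversible=yes | co2=none
fum: 1 FUM.m (abcd) -> 1 MAL.m (abcd) | reversible=yes | co2=none
mdh_m: 1 MAL.m (abcd) -> 1 OAA.m (abcd) | reversible=yes | co2=none
glu_syn: 1 AKG.m (abcde) -> 1 GLU.c (abcde) | reversible=no | co2=none
glusink: 1 GLU.c (abcde) -> 1 GLUSINK (abcde) | reversible=no | co2=none

# --- lumped phloem export (fixed composition; products are sinks) ---
export: 1 SUC.c + 0.1618 GLU.c + 0.0425 ASP.c + 0.01137 ALA.c -> 1 SINK | reversible=no | co2=none
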