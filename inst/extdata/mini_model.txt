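# Reduced leaf-like network used for scaled-down statistical experiments
# (confidence-interval coverage, scenario discrimination across seeds).
# One carboxylation, a triose-like pool, a one-carbon regeneration pool with
# a shunt-like CO2 release, an export branch, and two pyruvate
# decarboxylations standing in for TCA-associated and fatty-acid CO2 release.

@met CO2in carbons=1 source
@met CO2out carbons=1 sink
@met ACC.p carbons=2 dilution=yes
@met TRI.p carbons=3 dilution=yes
@met C1.p carbons=1
@met TRI.c carbons=3 dilution=yes
@met PYR.c carbons=3 dilution=yes
@met ACE.c carbons=2
@met CIT2.c carbons=2 dilution=yes
@met EXP carbons=3 sink
@met CH2O carbons=1 sink
@met FAS carbons=2 sink
@met CITS carbons=2 sink

carb: 1 ACC.p (ab) + 1 CO2in (c) -> 1 TRI.p (abc) | reversible=no | co2=none
regen: 1 TRI.p (abc) -> 1 C1.p (a) + 1 C1.p (b) + 1 C1.p (c) | reversible=no | co2=none
acc: 1 C1.p (a) + 1 C1.p (b) -> 1 ACC.p (ab) | reversible=no | co2=none
shuntm: 1 C1.p (a) -> 1 CO2out (a) | reversible=no | co2=release:shunt
c1sink: 1 C1.p (a) -> 1 CH2O (a) | reversible=no | co2=none
tpt: 1 TRI.p (abc) -> 1 TRI.c (abc) | reversible=yes | co2=none
expx: 1 TRI.c (abc) -> 1 EXP (abc) | reversible=no | co2=none
pyk: 1 TRI.c (abc) -> 1 PYR.c (abc) | reversible=no | co2=none
pdhm: 1 PYR.c (abc) -> 1 ACE.c (bc) + 1 CO2out (a) | reversible=no | co2=release:tca
fam: 1 PYR.c (abc) -> 1 FAS (bc) + 1 CO2out (a) | reversible=no | co2=release:fa
cs2: 1 ACE.c (ab) -> 1 CIT2.c (ab) | reversible=no | co2=none
citsink: 1 CIT2.c (ab) -> 1 CITS (ab) | reversible=no | co2=none
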