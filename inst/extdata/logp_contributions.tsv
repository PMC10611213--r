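# Atomic logP contributions, table version logp-1.
# Coarse atom-class consolidation of published atomic-contribution logP
# schemes (Crippen-style). Hydrogens contribute via the hcount of their heavy
# atom (classes H.C / H.het). Absolute values are approximate by design; the
# scale tracks lipophilicity well enough for 3/75-rule classification.
class	value	description
C.ar	0.294	aromatic carbon
C.carbonyl	-0.154	carbon double-bonded to oxygen
C.het	-0.203	aliphatic carbon bonded to N or O
C.al	0.141	other aliphatic carbon
N.ar	-0.493	aromatic nitrogen
N.amide	-0.597	amide nitrogen
N.amine	-1.019	aliphatic amine nitrogen
N.nitro	-0.300	nitro-group nitrogen
N.charged	-0.500	charged nitrogen
N.other	-0.600	other nitrogen
O.hydroxyl	-0.400	hydroxyl oxygen
O.carbonyl	-0.170	carbonyl oxygen
O.ether	-0.100	ether / ester oxygen
O.ar	-0.030	aromatic oxygen
O.charged	-1.000	charged oxygen
S.al	0.648	aliphatic sulfur
S.ar	0.620	aromatic sulfur
P	0.861	phosphorus
F	0.426	fluorine
Cl	0.690	chlorine
Br	0.851	bromine
I	0.886	iodine
B	0.180	boron
H.C	0.123	hydrogen on carbon
H.het	-0.100	hydrogen on heteroatom
other	0.000	fallback
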